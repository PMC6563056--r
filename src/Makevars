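# link against the system toolchain so the shared object loads with the
# run-time glibc
override CXX = g++
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
override CXX20 = g++
override CC = gcc
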