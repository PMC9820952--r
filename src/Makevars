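# CXXFLAGS arrives on the make command line, so a plain assignment cannot
# replace it; `override ... +=` appends these after the defaults, and the
# last -O/-march on the compile line wins.  -march=native is resolved on
# the machine that compiles the package.
override CXXFLAGS += -O3 -march=native -funroll-loops
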