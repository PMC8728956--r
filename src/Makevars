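# the transport loop is the package's hot path; build it at full
# optimization for the host CPU (compiled and run in the same environment)
CXXFLAGS = -O3 -march=native -fPIC
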