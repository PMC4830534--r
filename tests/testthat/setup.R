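# Pin linear-algebra threading to one thread: the suite's many small
# factorisations run faster without thread-pool contention.
Sys.setenv(
  OMP_NUM_THREADS = "1",
  OPENBLAS_NUM_THREADS = "1",
  MKL_NUM_THREADS = "1"
)
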