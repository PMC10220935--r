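# shared fixtures and independent oracles

# epochs data.frame with constant accelerations / mets
make_epochs <- function(mets, ac_fil = 50, ac_unfil = 50) {
  n <- length(mets)
  data.frame(epoch = seq_len(n),
             ac_fil = rep_len(ac_fil, n), ac_unfil = rep_len(ac_unfil, n),
             raw_zero = rep_len(ac_fil, n) == 0 & rep_len(ac_unfil, n) == 0,
             mets = mets)
}

# minute data.frame for one day
make_minutes <- function(mets, wear = TRUE, start = 0) {
  n <- length(mets)
  data.frame(minute_of_day = start + seq_len(n) - 1L,
             mets = mets, wear = rep_len(wear, n))
}

# brute-force run-length oracle for non-wear detection: minute i is
# non-wear iff it lies inside some window of >= run_min consecutive zeros
oracle_nonwear <- function(zero, run_min = 60) {
  n <- length(zero)
  wear <- rep(TRUE, n)
  i <- 1
  while (i <= n) {
    if (zero[i]) {
      j <- i
      while (j < n && zero[j + 1]) j <- j + 1
      if (j - i + 1 >= run_min) wear[i:j] <- FALSE
      i <- j + 1
    } else i <- i + 1
  }
  wear
}

# straight-line transcription of the three printed classification
# conditionals, independent of the package implementation
oracle_classify <- function(ac_fil, ac_unfil) {
  mapply(function(f, u) {
    if (f <= 29.9) "sedentary"
    else if (u / f >= 1.16) "non_locomotive"
    else "locomotive"
  }, ac_fil, ac_unfil)
}

oracle_met <- function(cls, ac_fil) {
  mapply(function(cl, f) {
    switch(cl,
           sedentary = 0.8823 + 0.0351 * f,
           non_locomotive = 1.3435 + 0.0196 * f,
           locomotive = 1.1128 + 0.0086 * f)
  }, cls, ac_fil)
}

seg_min <- function(kind, mins, ...) activity_segment(kind, mins * 60, ...)
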