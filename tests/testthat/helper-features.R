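# Qualitative trajectory features used by the regime tests.

# Number of plateaus of a population curve: phases of deceleration in
# the smoothed second difference of log population. A double-sigmoid
# (pseudo-stable level, boom, stable level) shows two such phases.
count_plateaus <- function(pop, window = 11, rel_threshold = 5e-3) {
  x <- log(pmax(pop, 1e-12))
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  sm <- sm[!is.na(sm)]
  d2 <- diff(sm, differences = 2)
  thr <- rel_threshold * max(abs(d2))
  s <- sign(d2)
  s[abs(d2) < thr] <- 0
  runs <- rle(s[s != 0])$values
  sum(runs == -1)
}

# Transient dip in a carrying-capacity series: a strict local maximum
# before the end (capacity rises, falls, then recovers).
has_capacity_bump <- function(capacity) {
  d <- diff(capacity)
  d <- d[d != 0]
  length(d) > 1 && any(diff(sign(d)) < 0)
}
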