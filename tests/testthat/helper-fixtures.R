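# Shared fixtures: all built in code, none stored on disk.

# A compact experiment with the full study structure (9 time points x 3
# replicates, matched vehicles) but a small panel, for fast module tests.
smallConfig <- function(nProbes = 200L, seed = 11L,
                        compounds = list(defaultArchetypes()[[1]],
                                         defaultArchetypes()[[5]])) {
  simulationConfig(nProbes = nProbes, pathways = defaultPathways(8L),
                   compounds = compounds, seed = seed)
}

# The standard time annotation of a built response set: 27 anchor columns
# (leave-one-out controls) + 3 replicates at each of 9 times.
standardTimes <- function(tp = c(1, 2, 4, 6, 8, 12, 16, 20, 24), nrep = 3L,
                          nAnchor = length(tp) * nrep) {
  c(rep(0, nAnchor), rep(tp, each = nrep))
}

# Toy count matrix with hand-checkable structure.
toyCounts <- function() {
  m <- matrix(c(10L, 20L, 30L, 40L, 50L, 60L), nrow = 3,
              dimnames = list(c("GENEA_1", "GENEB_2", "GENEC_3"),
                              c("s1", "s2")))
  m
}

# Exact hypergeometric upper tail by direct log-space summation; the
# independent oracle for the ORA p value.
hyperOracle <- function(k, m, n, N) {
  if (k == 0) return(1)
  i <- k:min(m, n)
  sum(exp(lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)))
}

# Dense-grid brute-force benchmark time: smallest grid t with
# |f(t) - f(0)| >= bmr, refined to the stated resolution.
gridBmt <- function(family, theta, bmr, tmax = 100, step = 1e-4) {
  f0 <- evalFamily(family, theta, 0)
  g <- function(t) abs(evalFamily(family, theta, t) - f0) - bmr
  # coarse pass then fine pass keeps this affordable at step 1e-4
  coarse <- seq(step, tmax, by = 0.01)
  gi <- g(coarse)
  idx <- which(gi >= 0)
  if (!length(idx)) return(NA_real_)
  lo <- if (idx[1] == 1) step else coarse[idx[1] - 1]
  fine <- seq(lo, coarse[idx[1]], by = step)
  fi <- g(fine)
  j <- which(fi >= 0)[1]
  if (j == 1) return(fine[1])
  # linear interpolation between the last negative and first non-negative
  t1 <- fine[j - 1]; t2 <- fine[j]
  t1 + (t2 - t1) * (-fi[j - 1]) / (fi[j] - fi[j - 1])
}
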