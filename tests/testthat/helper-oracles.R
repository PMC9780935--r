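# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: masses are summed directly from a local constant
# table, and isotope distributions are built from per-element multinomial
# enumeration rather than the package's atom-by-atom convolution.

oracle_masses <- c(C = 12, H = 1.00782503, N = 14.00307401,
                   O = 15.99491462, S = 31.97207117)
oracle_electron <- 0.00054858

oracle_isotopes <- list(
  C = list(offset = c(0, 1), mass = c(12, 13.00335484),
           p = c(0.9893, 0.0107)),
  H = list(offset = c(0, 1), mass = c(1.00782503, 2.01410178),
           p = c(0.999885, 0.000115)),
  N = list(offset = c(0, 1), mass = c(14.00307401, 15.00010890),
           p = c(0.99636, 0.00364)),
  O = list(offset = c(0, 1, 2), mass = c(15.99491462, 16.99913176,
                                         17.99915961),
           p = c(0.99757, 0.00038, 0.00205)),
  S = list(offset = c(0, 1, 2, 4),
           mass = c(31.97207117, 32.97145890, 33.96786700, 35.96708071),
           p = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# direct element-count parser for oracle use only
oracle_counts <- function(text) {
  m <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  el <- sub("[0-9]*$", "", m)
  n <- sub("^[A-Za-z]+", "", m)
  n <- ifelse(n == "", 1L, as.integer(n))
  tapply(n, el, sum)
}

oracle_mass <- function(text) {
  cnt <- oracle_counts(text)
  sum(oracle_masses[names(cnt)] * cnt)
}

# all compositions of n into m non-negative parts
oracle_compositions <- function(n, m) {
  if (m == 1L) return(matrix(n, ncol = 1))
  out <- list()
  for (k in 0:n) {
    rest <- oracle_compositions(n - k, m - 1L)
    out[[length(out) + 1L]] <- cbind(k, rest)
  }
  do.call(rbind, out)
}

# exact per-element offset distribution for `n` atoms of element `el`
oracle_element_dist <- function(el, n) {
  iso <- oracle_isotopes[[el]]
  comp <- oracle_compositions(n, length(iso$p))
  prob <- apply(comp, 1, function(k) stats::dmultinom(k, prob = iso$p))
  off <- as.vector(comp %*% iso$offset)
  mass <- as.vector(comp %*% iso$mass)
  agg_p <- tapply(prob, off, sum)
  agg_m <- tapply(prob * mass, off, sum)
  data.frame(offset = as.integer(names(agg_p)), p = as.numeric(agg_p),
             pm = as.numeric(agg_m))
}

# exact coarse pattern by combining per-element distributions over the
# cartesian product of offsets (no truncation)
oracle_pattern <- function(text) {
  cnt <- oracle_counts(text)
  dists <- lapply(names(cnt), function(el) oracle_element_dist(el, cnt[[el]]))
  combined <- data.frame(offset = 0L, p = 1, pm = 0)
  for (d in dists) {
    grid <- expand.grid(i = seq_len(nrow(combined)), j = seq_len(nrow(d)))
    off <- combined$offset[grid$i] + d$offset[grid$j]
    p <- combined$p[grid$i] * d$p[grid$j]
    pm <- combined$pm[grid$i] * d$p[grid$j] +
      combined$p[grid$i] * d$pm[grid$j]
    combined <- data.frame(
      offset = as.integer(names(tapply(p, off, sum))),
      p = as.numeric(tapply(p, off, sum)),
      pm = as.numeric(tapply(pm, off, sum)))
  }
  combined$mz <- combined$pm / combined$p
  combined$abundance <- combined$p / max(combined$p)
  combined
}

# random small formula as a string, for property tests
random_formula <- function() {
  counts <- c(C = sample(1:12, 1), H = sample(1:20, 1),
              N = sample(0:3, 1), O = sample(0:6, 1), S = sample(0:1, 1))
  counts <- counts[counts > 0]
  paste0(names(counts), counts, collapse = "")
}

# brute-force candidate count for the default rule set: cartesian product of
# rule multiplicities, global step bound, then per-multiset eligible
# conjugates (oxygen handle from any O-adding step, carboxyl handle from
# carboxylation)
oracle_default_library_size <- function(max_steps = 4L, h_max = 2L) {
  grid <- expand.grid(cooh = 0:1, oh = 0:1, diol = 0:1, h2 = 0:h_max)
  grid <- grid[rowSums(grid) <= max_steps, ]
  n <- nrow(grid)
  for (i in seq_len(nrow(grid))) {
    oxy <- grid$cooh[i] + grid$oh[i] + grid$diol[i] > 0
    carbox <- grid$cooh[i] > 0
    n <- n + 2 * oxy + 2 * carbox   # gluc+sulf | gly+taur
  }
  n
}
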