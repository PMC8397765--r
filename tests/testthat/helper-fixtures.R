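# Shared fixtures, generated in code. Memoized per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(make)
  .fixtures[[name]]
}

# default-geometry fiber phantom, 80^3, noiseless
fix_fiber80 <- function() fixture("fiber80", {
  make_fiber_phantom(phantom_spec(shape = c(80L, 80L, 80L), noise_sigma = 0,
                                  seed = 5))
})

# fat-cell phantom, 80^3
fix_fat80 <- function() fixture("fat80", {
  make_fat_cell_phantom(phantom_spec(shape = c(80L, 80L, 80L), noise_sigma = 0,
                                     seed = 6))
})

# exhaustive two-threshold Otsu oracle on a fixed histogram: a scalar
# double loop over every (t1 < t2) pair, computing the three class
# weights and means from prefix sums and scoring the between-class
# variance from its raw definition.
oracle_otsu3 <- function(counts, mids) {
  n <- length(counts)
  p <- counts / sum(counts)
  muT <- sum(p * mids)
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  best <- c(NA, NA)
  best_bcv <- -Inf
  for (t1 in 1:(n - 2)) {
    for (t2 in (t1 + 1):(n - 1)) {
      wA <- cw[t1]; wB <- cw[t2] - cw[t1]; wC <- 1 - cw[t2]
      if (wA <= 0 || wB <= 0 || wC <= 0) next
      mA <- cm[t1] / wA
      mB <- (cm[t2] - cm[t1]) / wB
      mC <- (cm[n] - cm[t2]) / wC
      bcv <- wA * (mA - muT)^2 + wB * (mB - muT)^2 + wC * (mC - muT)^2
      if (bcv > best_bcv) {
        best_bcv <- bcv
        best <- c(t1, t2)
      }
    }
  }
  best
}

# random two- or three-component Gaussian mixture sample
random_mixture <- function(n = 20000L) {
  k <- sample(2:3, 1L)
  means <- sort(stats::runif(k, 0, 10))
  sds <- stats::runif(k, 0.2, 1.5)
  w <- stats::runif(k, 0.2, 1)
  w <- w / sum(w)
  comp <- sample.int(k, n, replace = TRUE, prob = w)
  stats::rnorm(n, means[comp], sds[comp])
}
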