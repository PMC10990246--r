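# Shared fixtures, built in code.

# small well-separated 2-D ordinal cohort for fit/predict checks
toy_training_set <- function(n = 10, d = 2, sep = 3, seed = 1) {
  set.seed(seed)
  training_set(
    X1 = matrix(rnorm(n * d), n, d),
    X2 = matrix(rnorm(n * d, mean = sep), n, d),
    X12 = matrix(rnorm(n * d, mean = sep / 2), n, d),
    X0 = matrix(rnorm(n * d, mean = -sep), n, d)
  )
}

# random small instance generator used by the oracle-equivalence suites
random_small_instance <- function(d = NULL) {
  if (is.null(d)) d <- sample(1:3, 1)
  ts <- training_set(
    X1 = matrix(rnorm(3 * d), 3, d),
    X2 = matrix(rnorm(3 * d, 1.5), 3, d),
    X12 = matrix(rnorm(2 * d, 0.8), 2, d),
    X0 = matrix(rnorm(4 * d, -2), 4, d)
  )
  list(ts = ts, d = d,
       C1 = 10^runif(1, -1, 1), C2 = 10^runif(1, -1, 1))
}

# tiny 2-contrast stack with hand-set geometry (16x16)
tiny_stack <- function(seed = 1, contrasts = c("A", "B")) {
  set.seed(seed)
  shape <- c(16L, 16L)
  aoi <- matrix(FALSE, 16, 16); aoi[3:14, 3:14] <- TRUE
  ce <- matrix(FALSE, 16, 16); ce[6:11, 6:11] <- TRUE
  ne <- aoi & !ce
  normal <- matrix(FALSE, 16, 16)  # disjoint dummy corner region
  normal[1:2, 1:2] <- TRUE
  imgs <- lapply(seq_along(contrasts),
                 function(i) matrix(rnorm(256, mean = i), 16, 16))
  names(imgs) <- contrasts
  contrast_stack(imgs, aoi, ce, ne, normal)
}

# small bank so feature extraction stays fast in unit tests
small_bank <- function() feature_bank_config(
  gabor_frequencies = c(0.2, 0.4), gabor_orientations = c(0, 90),
  gabor_extra = list())
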