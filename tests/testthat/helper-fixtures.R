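# Shared fixture builders.  All fixtures are generated in code.

# toy atlas: `sizes` ROIs per network, networks named A, B, C, ...
toy_atlas <- function(sizes = c(2, 2)) {
  nets <- LETTERS[seq_along(sizes)]
  roi <- unlist(mapply(function(nw, k) paste0(tolower(nw), seq_len(k)),
                       nets, sizes, SIMPLIFY = FALSE))
  hemi <- rep(c("left", "right"), length.out = length(roi))
  mcn_atlas(roi, hemi, rep(nets, sizes))
}

# small valid cohort over the default atlas, deterministic
toy_cohort <- function(n = 3L, atlas = default_atlas(), seed = 42L) {
  set.seed(seed)
  id <- sprintf("S%02d", seq_len(n))
  age1 <- 30 + seq_len(n) / 10
  age2 <- 41 + seq_len(n) / 10
  volumes <- data.frame(subject_id = id, age_scan1_weeks = age1,
                        age_scan2_weeks = age2, stringsAsFactors = FALSE)
  for (roi in atlas$roi) {
    v1 <- stats::runif(n, 1000, 4000)
    volumes[[paste0(roi, "_t1")]] <- v1
    volumes[[paste0(roi, "_t2")]] <- v1 * stats::runif(n, 1.2, 2.0)
  }
  covariates <- data.frame(
    subject_id = id, gender = rep_len(0:1, n),
    total_brain_volume = stats::runif(n, 150000, 220000),
    gestational_age = stats::runif(n, 24, 28),
    age_scan1_weeks = age1, age_scan2_weeks = age2,
    ivh = rep_len(c(0, 1, 0), n), surgeries = rep_len(0:2, n),
    prenatal_steroids = 1, postnatal_steroids = rep_len(c(0, 0, 1), n),
    morphine_days = rep_len(c(0, 3, 10), n), stringsAsFactors = FALSE)
  list(volumes = volumes, covariates = covariates, atlas = atlas)
}

# association object with prescribed Fisher-z edge weights (for
# thresholding fixtures where exact ranks matter)
fake_assoc <- function(z, n = 20L) {
  z[lower.tri(z)] <- t(z)[lower.tri(z)]   # upper triangle is authoritative
  diag(z) <- 0
  structure(list(r = tanh(z), z = z, n = n, group = NA_character_),
            class = "mcn_association")
}

# independent BH step-up implementation (oracle for fdr_adjust)
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

# brute-force externally studentized residuals by n leave-one-out refits
loo_studentized <- function(y, X = NULL) {
  n <- length(y)
  df <- if (is.null(X)) data.frame(y = y) else data.frame(y = y, X)
  fml <- if (is.null(X)) y ~ 1 else y ~ .
  fit <- stats::lm(fml, data = df)
  e <- stats::resid(fit)
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  vapply(seq_len(n), function(i) {
    s <- summary(stats::lm(fml, data = df[-i, , drop = FALSE]))$sigma
    e[i] / (s * sqrt(1 - h[i]))
  }, numeric(1))
}
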