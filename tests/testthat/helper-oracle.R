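# Brute-force quantile-regression oracle: an optimal basic solution of the
# pinball-loss LP interpolates p observations, so for tiny n we enumerate
# every non-singular p-subset, solve it exactly, and keep the minimal loss.
# Independent of the interior-point path used by the package.
oracle_rq <- function(X, y, tau) {
  n <- nrow(X)
  p <- ncol(X)
  best_loss <- Inf
  best_coef <- NULL
  for (s in utils::combn(n, p, simplify = FALSE)) {
    Xs <- X[s, , drop = FALSE]
    if (abs(det(Xs)) < 1e-10) next
    b <- solve(Xs, y[s])
    l <- pinball_loss(y, drop(X %*% b), tau)
    if (l < best_loss) {
      best_loss <- l
      best_coef <- b
    }
  }
  list(loss = best_loss, coefficients = best_coef)
}

# small hand-buildable participant table for preprocessing tests
toy_participants <- function() {
  tibble::tibble(
    participant_id = sprintf("P%02d", 1:5),
    measurement_date = as.Date("2021-06-01") + 0:4,
    age_years = c(40, 52, 61, 35, 47),
    years_since_diagnosis = c(5, 12, 20, 2, 9),
    eq5d_index = c(88, 92, NA, 75, 96),
    vas = c(80L, NA, 70L, NA, 90L)
  )
}

# single-domain tariff used for hand-derived index values
single_domain_value_set <- function() {
  value_set(
    data.frame(domain = "mobility", level = 1:2, decrement = c(0, 0.25)),
    constant = 1, u_min = -0.5, version = "toy-one-domain"
  )
}

# draw from a known baseline-category multinomial logit (K = 3) for
# parameter-recovery tests; category 1 is the reference. With `seed = NULL`
# the draw continues the current RNG stream (one master stream across
# replicates avoids dependence between sequentially seeded streams).
simulate_multinomial <- function(n, beta_low, beta_high, seed = NULL) {
  draw <- function() {
    z <- stats::rbinom(n, 1, 0.4)
    w <- stats::rnorm(n)
    X <- cbind(1, z, w)
    eta_low <- drop(X %*% beta_low)
    eta_high <- drop(X %*% beta_high)
    denom <- 1 + exp(eta_low) + exp(eta_high)
    u <- stats::runif(n)
    p_low <- exp(eta_low) / denom
    p_high <- exp(eta_high) / denom
    g <- ifelse(u < p_low, "low", ifelse(u < p_low + p_high, "high", "normal"))
    tibble::tibble(group = g, z = z, w = w)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
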