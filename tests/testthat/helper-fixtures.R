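# fixtures and independent oracles shared across test files

# small deterministic aggregated trial
toy_trial <- function() {
  trial_dataset(paste0("c", 1:6), rep(c(0L, 1L), each = 3),
                c(1L, 2L, 3L, 4L, 5L, 6L), rep(10L, 6))
}

random_trial <- function(n = 10, mmax = 30, p = 0.3) {
  m <- sample(2:mmax, n, replace = TRUE)
  trial_dataset(paste0("c", seq_len(n)), rep(c(0L, 1L), each = n / 2),
                rbinom(n, m, p), m)
}

# brute-force GEE sandwich assembly at individual level, directly from the
# printed matrix formulas; V_W is the compound-symmetric working covariance
gee_sandwich_bruteforce <- function(data, beta, alpha = 0,
                                    correction = "none", fg_bound = 0.75) {
  mkx <- function(arm, m) cbind(rep(1, m), rep(arm, m))
  mu_of <- function(arm) plogis(beta[1] + beta[2] * arm)
  bread <- matrix(0, 2, 2)
  for (j in seq_len(nrow(data))) {
    m <- data$size[j]; arm <- data$arm[j]
    mu <- mu_of(arm); v <- mu * (1 - mu)
    X <- mkx(arm, m)
    D <- v * X                                  # d mu / d beta', m x 2
    Vw <- v * ((1 - alpha) * diag(m) + alpha * matrix(1, m, m))
    bread <- bread + t(D) %*% solve(Vw) %*% D
  }
  V_M <- solve(bread)
  meat <- matrix(0, 2, 2)
  ok <- TRUE
  for (j in seq_len(nrow(data))) {
    m <- data$size[j]; arm <- data$arm[j]
    mu <- mu_of(arm); v <- mu * (1 - mu)
    yvec <- c(rep(1, data$events[j]), rep(0, m - data$events[j]))
    X <- mkx(arm, m)
    D <- v * X
    Vw <- v * ((1 - alpha) * diag(m) + alpha * matrix(1, m, m))
    Vwi <- solve(Vw)
    r <- yvec - mu
    covy <- tcrossprod(r)
    if (correction == "none") {
      meat <- meat + t(D) %*% Vwi %*% covy %*% Vwi %*% D
    } else if (correction == "KC") {
      H <- diag(m) - D %*% V_M %*% t(D) %*% Vwi
      e <- eigen(H)
      if (any(Re(e$values) <= 0)) { ok <- FALSE; next }
      Hs <- Re(e$vectors %*% diag(Re(e$values)^(-1 / 2)) %*% solve(e$vectors))
      meat <- meat + t(D) %*% Vwi %*% Hs %*% covy %*% t(Hs) %*% Vwi %*% D
    } else {
      q <- diag(t(D) %*% Vwi %*% D %*% V_M)
      A <- diag((1 - pmin(fg_bound, q))^(-1 / 2))
      meat <- meat + A %*% t(D) %*% Vwi %*% covy %*% Vwi %*% D %*% A
    }
  }
  out <- V_M %*% meat %*% V_M
  attr(out, "ok") <- ok
  out
}
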