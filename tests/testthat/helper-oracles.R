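# Independent oracles used across the suite.

disease_params <- function(...) update_rates(dhe_params("disease"), ...)
control_params <- function(...) update_rates(dhe_params("control"), ...)

# System matrix of a constant-coefficient variant. For the efflux variant
# this is only valid for mu = 1 (constant hazard k6 on n4).
variant_matrix <- function(variant, p) {
  A <- matrix(0, 4, 4)
  if (variant == "reversible_two_branch") {
    A[1, ] <- c(-(p$kab + p$kac), p$kba, p$kca, 0)
    A[2, ] <- c(p$kab, -p$kba, 0, 0)
    A[3, ] <- c(p$kac, 0, -p$kca, 0)
    return(A)
  }
  loss1 <- p$k1 + if (variant %in% c("open_four", "efflux_two_pathway"))
    p$k5 else 0
  A[1, ] <- c(-loss1, 0, p$k3, 0)
  A[2, ] <- c(p$k1, -p$k2, 0, 0)
  A[3, ] <- c(0, p$k2, -(p$k3 + p$k4), p$km4)
  loss4 <- p$km4 + if (variant == "efflux_two_pathway") {
    stopifnot(p$mu == 1)
    p$k6
  } else 0
  A[4, ] <- c(0, 0, p$k4, -loss4)
  A
}

# Matrix-exponential solution of dy/dt = A y (+ b for open_four) at the
# given times; independent of the lsoda integration path.
expm_solution <- function(variant, p, init, times) {
  A <- variant_matrix(variant, p)
  if (variant == "open_four") {
    M <- rbind(cbind(A, c(p$v0, 0, 0, 0)), 0)
    y0 <- c(init, 1)
    t(vapply(times, function(t)
      as.numeric(Matrix::expm(M * t) %*% y0)[1:4], numeric(4)))
  } else {
    t(vapply(times, function(t)
      as.numeric(Matrix::expm(A * t) %*% init), numeric(4)))
  }
}

# Steady state of the open system by direct linear solve (A n = -b),
# independent of the closed-form expressions in the package.
solve_steady_state <- function(p) {
  A <- variant_matrix("open_four", p)
  as.numeric(solve(A, -c(p$v0, 0, 0, 0)))
}

# Random positive rate set in the experimentally relevant range.
random_rates <- function(variant) {
  r <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  switch(variant,
    closed_three = rate_constants(k1 = r(.005, .1), k2 = r(.05, .5),
                                  k3 = r(.02, .3)),
    closed_four = rate_constants(k1 = r(.005, .1), k2 = r(.05, .5),
                                 k3 = r(.02, .3), k4 = r(.002, .03),
                                 km4 = r(.002, .1)),
    # v0 kept small so trajectories stay O(1) over the test windows
    open_four = rate_constants(k1 = r(.005, .1), k2 = r(.05, .5),
                               k3 = r(.02, .3), k4 = r(.002, .03),
                               km4 = r(.002, .1), v0 = r(1e-4, 2e-3),
                               k5 = r(1e-3, .01)),
    efflux_two_pathway = rate_constants(k1 = r(.005, .1), k2 = r(.05, .5),
                                        k3 = r(.02, .3), k4 = r(.002, .03),
                                        km4 = r(.002, .1), k5 = r(1e-4, .01),
                                        k6 = r(5e-4, .005), mu = 1))
}
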