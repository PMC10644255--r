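# Monte-Carlo model-recovery study at 2% additive noise, shared between
# the fitting property tests and the acceptance suite. Memoised so the
# study runs once per session regardless of which test file asks first.
#
# Two arms:
#   biphasic (n = 100) — truth: four-compartment disease rates; both
#                 variants fitted; records the BIC winner and the
#                 closed_four estimates (parameter-recovery sample).
#   single_phase (n = 50) — truth: three-compartment control rates; both
#                 variants fitted; records the BIC winner.
mc_model_recovery <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n_rep <- 100L
    n_rep_sp <- 50L
    # log-spaced chase times: resolves both the fast RE exchange
    # (1/k2 ~ 2 min) and the slow ILV loading (1/km4 ~ 4 h)
    grid <- c(0, 2.5, 5, 10, 20, 40, 80, 160, 240, 360, 480, 600)
    truth4 <- unlist(unclass(dhe_params("disease")))[
      c("k1", "k2", "k3", "k4", "km4")]
    guess4 <- c(k1 = .05, k2 = .3, k3 = .1, k4 = .01, km4 = .005)
    guess3 <- c(k1 = .05, k2 = .3, k3 = .1)

    fit_both <- function(ds) {
      f4 <- global_fit(ds, "closed_four", initial_guess = guess4)
      f3 <- global_fit(ds, "closed_three", initial_guess = guess3)
      list(f4 = f4, f3 = f3,
           winner = if (f4$bic < f3$bic) "closed_four" else "closed_three")
    }

    bi_winner <- character(n_rep)
    bi_est <- matrix(NA_real_, n_rep, 5,
                     dimnames = list(NULL, names(truth4)))
    for (i in seq_len(n_rep)) {
      ds <- generate_pulse_chase(
        dhe_params("disease"), grid = grid,
        noise = noise_spec(sigma = 0.02, seed = 9000L + i))
      r <- fit_both(ds)
      bi_winner[i] <- r$winner
      bi_est[i, ] <- r$f4$estimates[names(truth4)]
    }

    sp_winner <- character(n_rep_sp)
    for (i in seq_len(n_rep_sp)) {
      ds <- generate_pulse_chase(
        dhe_params("control"), variant = "closed_three", grid = grid,
        noise = noise_spec(sigma = 0.02, seed = 17000L + i))
      sp_winner[i] <- fit_both(ds)$winner
    }

    cache <<- list(truth4 = truth4,
                   biphasic_winner = bi_winner,
                   biphasic_estimates = bi_est,
                   single_phase_winner = sp_winner)
    cache
  }
})
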