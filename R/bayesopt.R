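# Gaussian-process Bayesian hyperparameter optimization with a
# two-stage (coarse then contracted) search and expected-improvement
# acquisition.

#' Hyperparameter search space
#'
#' Continuous ranges are searched on a linear scale; the batch size is a
#' discrete choice.
#'
#' @param lr_range learning-rate range.
#' @param wd_range weight-decay range. The default upper bound (1e-2) is
#'   wide enough to contain the shipped default optimum of [train_config()].
#' @param batch_choices candidate batch sizes.
#' @param epoch_range range of maximum epochs.
#' @return a `hyperparam_space` list.
#' @export
hyperparam_space <- function(lr_range = c(1e-4, 1e-3),
                             wd_range = c(1e-4, 1e-2),
                             batch_choices = c(64L, 128L),
                             epoch_range = c(100L, 300L)) {
  stopifnot(lr_range[1] < lr_range[2], wd_range[1] < wd_range[2],
            length(batch_choices) >= 1L, epoch_range[1] < epoch_range[2])
  structure(list(lr_range = lr_range, wd_range = wd_range,
                 batch_choices = as.integer(batch_choices),
                 epoch_range = as.integer(epoch_range)),
            class = "hyperparam_space")
}

space_dim <- function(space) 4L

# Map a point in [0,1]^4 to a named configuration.
space_decode <- function(u, space) {
  list(
    learning_rate = space$lr_range[1] + u[1] * diff(space$lr_range),
    weight_decay = space$wd_range[1] + u[2] * diff(space$wd_range),
    batch_size = space$batch_choices[
      pmin(length(space$batch_choices),
           1L + floor(u[3] * length(space$batch_choices)))],
    max_epochs = as.integer(round(space$epoch_range[1] +
                                    u[4] * diff(space$epoch_range)))
  )
}

# GP with RBF kernel on the unit cube; returns predictive mean/sd.
gp_fit <- function(U, y, lengthscale = 0.25, nugget = 1e-6) {
  y_mu <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  ys <- (y - y_mu) / y_sd
  D2 <- as.matrix(stats::dist(U))^2
  K <- exp(-0.5 * D2 / lengthscale^2) + diag(nugget, nrow(U))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(U = U, L = L, alpha = alpha, y_mu = y_mu, y_sd = y_sd,
       lengthscale = lengthscale)
}

gp_predict <- function(fit, Unew) {
  # RBF cross-kernel via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2ab
  cross <- exp(-0.5 * outer(rowSums(Unew^2), rowSums(fit$U^2), `+`) /
                 fit$lengthscale^2 +
                 (Unew %*% t(fit$U)) / fit$lengthscale^2)
  mu <- as.vector(cross %*% fit$alpha) * fit$y_sd + fit$y_mu
  v <- forwardsolve(t(fit$L), t(cross))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mu = mu, sd = sqrt(s2) * fit$y_sd)
}

expected_improvement <- function(mu, sd, best) {
  imp <- best - mu
  z <- imp / sd
  ei <- imp * stats::pnorm(z) + sd * stats::dnorm(z)
  ei[sd < 1e-12] <- 0
  ei
}

run_stage <- function(objective, space, lower, upper, budget, n_init,
                      evals, n_cand = 500L) {
  dim <- space_dim(space)
  draw <- function(m) {
    matrix(stats::runif(m * dim), m, dim) %*% diag(upper - lower) +
      matrix(lower, m, dim, byrow = TRUE)
  }
  try_eval <- function(u) {
    cfg <- space_decode(u, space)
    val <- tryCatch(objective(cfg), error = function(e) NA_real_)
    if (!is.null(val) && length(val) == 1L && is.finite(val)) {
      evals$U <- rbind(evals$U, u)
      evals$y <- c(evals$y, val)
    } else {
      evals$failed <- evals$failed + 1L
    }
    evals$n <- evals$n + 1L
    evals
  }
  used <- 0L
  for (k in seq_len(min(n_init, budget))) {
    evals <- try_eval(draw(1L)[1L, ])
    used <- used + 1L
  }
  while (used < budget) {
    if (length(evals$y) >= 2L) {
      fit <- gp_fit(evals$U, evals$y)
      cand <- draw(n_cand)
      pred <- gp_predict(fit, cand)
      ei <- expected_improvement(pred$mu, pred$sd, min(evals$y))
      u <- cand[which.max(ei), ]
    } else {
      u <- draw(1L)[1L, ]
    }
    evals <- try_eval(u)
    used <- used + 1L
  }
  evals
}

#' GP-based Bayesian hyperparameter search
#'
#' Two-stage search: stage 1 explores the full space with a Gaussian
#' process surrogate (RBF kernel) and expected-improvement acquisition;
#' stage 2 re-searches a box contracted to +/-25% around the stage-1
#' incumbent (clipped to the space). All proposals lie inside the space
#' and the total number of objective evaluations equals `budget`; failed
#' evaluations are skipped (they consume budget but do not enter the
#' surrogate).
#'
#' @param objective function taking a configuration list
#'   (`learning_rate`, `weight_decay`, `batch_size`, `max_epochs`) and
#'   returning a finite scalar to minimize (e.g. validation loss).
#' @param space a [hyperparam_space()].
#' @param budget total number of objective evaluations (>= 2).
#' @param seed RNG seed.
#' @param stage1_frac fraction of the budget spent on the coarse stage.
#' @return list with `best` (the incumbent configuration), `best_value`,
#'   and `trials` (data.frame of all successful evaluations).
#' @export
bayes_optimize <- function(objective, space = hyperparam_space(),
                           budget = 25L, seed = 1L, stage1_frac = 0.6) {
  stopifnot(inherits(space, "hyperparam_space"), budget >= 2L)
  set.seed(seed)
  dim <- space_dim(space)
  evals <- list(U = matrix(numeric(), 0L, dim), y = numeric(),
                failed = 0L, n = 0L)
  b1 <- max(2L, ceiling(budget * stage1_frac))
  b2 <- budget - b1
  evals <- run_stage(objective, space, rep(0, dim), rep(1, dim), b1,
                     n_init = min(5L, b1), evals = evals)
  if (b2 > 0L && length(evals$y) > 0L) {
    inc <- evals$U[which.min(evals$y), ]
    lower <- pmax(0, inc - 0.25)
    upper <- pmin(1, inc + 0.25)
    evals <- run_stage(objective, space, lower, upper, b2,
                       n_init = min(3L, b2), evals = evals)
  }
  if (length(evals$y) == 0L) stop("all objective evaluations failed")
  ibest <- which.min(evals$y)
  trials <- do.call(rbind, lapply(seq_along(evals$y), function(i) {
    cfg <- space_decode(evals$U[i, ], space)
    data.frame(learning_rate = cfg$learning_rate,
               weight_decay = cfg$weight_decay,
               batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
               value = evals$y[i])
  }))
  list(best = space_decode(evals$U[ibest, ], space),
       best_value = evals$y[ibest], trials = trials,
       n_evaluations = evals$n, n_failed = evals$failed)
}
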