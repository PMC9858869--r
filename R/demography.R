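#' Monte-Carlo expected joint SFS under a demographic model
#'
#' Simulates `n_loci` genealogies for a projection-sized sample and
#' accumulates each branch's length into the unfolded entry given by its
#' descendant counts per deme, then folds, masks the monomorphic corners and
#' normalizes to proportions. Working on branch lengths rather than dropped
#' mutations makes the expectation mutation-rate-free and lower-variance.
#' Zero cells are floored at `floor_prop` before normalization so the
#' composite likelihood stays finite.
#'
#' @param params a [demographic_params()].
#' @param model a [model_spec()].
#' @param projection haploid sample sizes `(n1, n2)`.
#' @param n_loci number of simulated genealogies.
#' @param floor_prop minimum proportion for empty unmasked cells.
#' @return a [joint_sfs()] of proportions (unmasked entries sum to 1).
#' @export
expected_sfs <- function(params, model, projection, n_loci = 1e5,
                         floor_prop = 1e-10) {
  stopifnot(n_loci >= 1)
  ep <- migration_epoch(params, model)
  m1 <- if (model$name == "SI") 0 else params$mjm
  m2 <- if (model$name == "SI") 0 else params$mmj
  u <- .sfs_branch_cpp(as.integer(projection[1]), as.integer(projection[2]),
                       params$N_pma, params$N_pja, params$N_anc, params$T_S,
                       ep[1], ep[2], m1, m2, as.integer(n_loci))
  f <- fold_joint_sfs(u)
  um <- unmasked_entries(dim(f))
  tot <- sum(f[um])
  if (tot <= 0) stop("simulation failure: all-zero expected spectrum",
                     call. = FALSE)
  p <- f / tot
  p[um & p == 0] <- floor_prop
  p[um] <- p[um] / sum(p[um])
  p[!um] <- 0
  joint_sfs(p, projection, folded = TRUE)
}

sfs_checksum <- function(obs) {
  v <- as.numeric(obs$counts)
  sum(v * seq_along(v)) + 1000 * sfs_total(obs)
}

#' Composite log10-likelihood of an observed SFS
#'
#' `sum(obs * log10(exp))` over unmasked entries: the multinomial
#' log-likelihood treating sites as independent.
#'
#' @param obs [joint_sfs()] of counts (site mass).
#' @param expected [joint_sfs()] of strictly positive unmasked proportions.
#' @return log10 composite likelihood (numeric scalar).
#' @export
composite_log_likelihood <- function(obs, expected) {
  if (!all(obs$projection == expected$projection) ||
      !identical(obs$folded, expected$folded))
    stop("observed and expected SFS have mismatched shape or folding",
         call. = FALSE)
  um <- unmasked_entries(dim(obs$counts))
  if (any(expected$counts[um] <= 0))
    stop("expected proportions must be strictly positive on unmasked entries",
         call. = FALSE)
  sum(obs$counts[um] * log10(expected$counts[um]))
}

#' Search settings for [fit_model()]
#'
#' Derivative-free simplex search in transformed space (log10 sizes and
#' split time, logit epoch fractions, log10 migration), multi-restart, with
#' common random numbers within each restart to tame Monte-Carlo noise.
#'
#' @param n_restarts independent restarts from random starting points.
#' @param n_loci genealogies per likelihood evaluation in the coarse phase.
#' @param polish_n_loci genealogies per evaluation in the polish phase run
#'   from each coarse optimum (lower Monte-Carlo noise near the optimum).
#' @param final_n_loci genealogies for the final (comparable) evaluation of
#'   each restart's optimum.
#' @param maxit simplex iterations for the coarse phase.
#' @param polish_maxit simplex iterations for the polish phase.
#' @param n_polish how many of the best coarse optima are polished.
#' @param refine_n_loci unused reserve (the refinement pass runs on the
#'   final-evaluation surface itself).
#' @param refine_maxit simplex iterations of a refinement pass on the single
#'   best polished candidate, run with the shared final-evaluation seed.
#' @param size_bounds,time_bounds,mig_bounds search boxes (natural scale).
#' @return a `search_config`.
#' @export
search_config <- function(n_restarts = 10, n_loci = 10000,
                          polish_n_loci = 4 * n_loci,
                          final_n_loci = 50000, maxit = 320,
                          polish_maxit = ceiling(maxit / 2),
                          n_polish = 2,
                          refine_n_loci = 4 * polish_n_loci,
                          refine_maxit = 40,
                          size_bounds = c(10, 1e6),
                          time_bounds = c(1, 1e7),
                          mig_bounds = c(1e-10, 0.5)) {
  structure(list(n_restarts = n_restarts, n_loci = n_loci,
                 polish_n_loci = polish_n_loci,
                 final_n_loci = final_n_loci, maxit = maxit,
                 polish_maxit = polish_maxit, n_polish = n_polish,
                 refine_n_loci = refine_n_loci, refine_maxit = refine_maxit,
                 size_bounds = size_bounds, time_bounds = time_bounds,
                 mig_bounds = mig_bounds),
            class = "search_config")
}

# transformed-space boxes, in the order of the free parameter names
free_boxes <- function(free, search) {
  lapply(free, function(nm) {
    switch(nm,
      N_anc = , N_pma = , N_pja = log10(search$size_bounds),
      T_S = log10(search$time_bounds),
      T_1 = , T_2 = c(-8, 8),               # logit of the epoch fraction
      mmj = , mjm = log10(search$mig_bounds))
  })
}

transform_to_params <- function(x, model, free = model$free, fixed = list()) {
  v <- setNames(as.list(rep(NA_real_, 8)),
                c("N_anc", "N_pma", "N_pja", "T_S", "T_1", "T_2", "mmj", "mjm"))
  names(x) <- free
  for (nm in c("N_anc", "N_pma", "N_pja", "T_S"))
    v[[nm]] <- if (nm %in% names(fixed)) fixed[[nm]] else 10^x[[nm]]
  if ("T_1" %in% model$free)
    v$T_1 <- if ("T_1" %in% names(fixed)) fixed$T_1
             else v$T_S * stats::plogis(x[["T_1"]])
  if ("T_2" %in% model$free)
    v$T_2 <- if ("T_2" %in% names(fixed)) fixed$T_2
             else v$T_1 * stats::plogis(x[["T_2"]])
  mig <- function(nm) {
    if (!nm %in% model$free) return(0)
    if (nm %in% names(fixed)) return(fixed[[nm]])
    10^x[[nm]]
  }
  v$mmj <- mig("mmj"); v$mjm <- mig("mjm")
  demographic_params(v$N_anc, v$N_pma, v$N_pja, v$T_S, v$T_1, v$T_2,
                     v$mmj, v$mjm)
}

# inverse of transform_to_params: starting coordinates from natural values
params_to_x <- function(params, model, search, free = model$free) {
  boxes <- free_boxes(free, search)
  lo <- vapply(boxes, `[`, 0, 1); hi <- vapply(boxes, `[`, 0, 2)
  x <- vapply(seq_along(free), function(i) {
    nm <- free[i]
    val <- switch(nm,
      N_anc = log10(params$N_anc), N_pma = log10(params$N_pma),
      N_pja = log10(params$N_pja), T_S = log10(params$T_S),
      T_1 = stats::qlogis(min(max(params$T_1 / params$T_S, 1e-3), 1 - 1e-3)),
      T_2 = stats::qlogis(min(max(params$T_2 / params$T_1, 1e-3), 1 - 1e-3)),
      mmj = log10(max(params$mmj, 1e-9)),
      mjm = log10(max(params$mjm, 1e-9)))
    min(max(val, lo[i]), hi[i])
  }, 0)
  setNames(x, free)
}

#' Fit one demographic model to an observed SFS
#'
#' Maximizes the composite likelihood over the model's free parameters by
#' multi-restart Nelder-Mead in transformed space. Each restart fixes its
#' own random-number stream for the Monte-Carlo expected SFS (common random
#' numbers), and every restart's optimum is re-evaluated with a shared seed
#' and `final_n_loci` genealogies so restarts (and models) are compared on
#' equal footing. Identical RNG state and settings give identical results.
#'
#' @param obs observed [joint_sfs()] of counts, built without MAF filtering.
#' @param model a [model_spec()].
#' @param search a [search_config()].
#' @param eval_seed seed for the final comparable evaluation; supply the
#'   same value across models when computing AICs. Drawn from the RNG if
#'   `NULL`.
#' @param inits optional list of [demographic_params()] used as additional
#'   (warm) starting points on top of the random restarts.
#' @param fixed named list of parameters held at known values rather than
#'   estimated. Because the composite likelihood works on polymorphic-site
#'   proportions, all sizes and times can be rescaled jointly (with
#'   migration rescaled inversely) without changing the expected spectrum;
#'   fixing one size or time anchors that scale, exactly as fastsimcoal-style
#'   analyses anchor SNP-only spectra with an externally estimated
#'   parameter. Fixed parameters do not count towards k in the AIC.
#' @return a `demog_fit`: `model`, `params` ([demographic_params()]),
#'   `logCL10`, `AIC`, `restarts` tibble, `obs_total`, `obs_checksum`,
#'   `projection`, `search`, `eval_seed`.
#' @export
fit_model <- function(obs, model, search = search_config(), eval_seed = NULL,
                      inits = NULL, fixed = list()) {
  if (isTRUE(attr(obs, "maf_filtered")))
    stop("SFS built from MAF-filtered data", call. = FALSE)
  if (length(fixed) && !all(names(fixed) %in% model$free))
    stop("fixed parameters must be free parameters of the model",
         call. = FALSE)
  free <- setdiff(model$free, names(fixed))
  boxes <- free_boxes(free, search)
  lo <- vapply(boxes, `[`, 0, 1); hi <- vapply(boxes, `[`, 0, 2)
  proj <- obs$projection
  if (is.null(eval_seed)) eval_seed <- sample.int(.Machine$integer.max, 1)
  starts <- lapply(seq_len(search$n_restarts),
                   function(r) runif(length(lo), lo, hi))
  starts <- c(starts, lapply(inits, params_to_x, model = model,
                             search = search, free = free))
  n_starts <- length(starts)
  restart_seeds <- matrix(sample.int(.Machine$integer.max, 2 * n_starts),
                          ncol = 2)
  # the empty-cell floor scales with the Monte-Carlo resolution: a fixed
  # tiny floor makes the surrogate likelihood jump by ~10 log-units per
  # observed site whenever a low-mass cell comes up empty at small n_loci
  objective <- function(x, crn_seed, n_loci) {
    xc <- pmin(pmax(x, lo), hi)
    pen <- sum((x - xc)^2)
    params <- transform_to_params(xc, model, free, fixed)
    set.seed(crn_seed)
    e <- expected_sfs(params, model, proj, n_loci = n_loci,
                      floor_prop = 0.5 / n_loci)
    -composite_log_likelihood(obs, e) + 1e3 * pen
  }
  # every candidate (and the refinement pass) is scored on one shared
  # common-random-numbers surface, so likelihood *contrasts* between
  # candidates and between models are far less noisy than absolute values
  final_eval <- function(params) {
    set.seed(eval_seed)
    e <- expected_sfs(params, model, proj, n_loci = search$final_n_loci,
                      floor_prop = 0.5 / search$final_n_loci)
    composite_log_likelihood(obs, e)
  }
  # coarse phase: cheap noisy simplex from every start
  coarse <- vector("list", n_starts)
  for (r in seq_len(n_starts)) {
    opt <- optim(starts[[r]], objective, crn_seed = restart_seeds[r, 1],
                 n_loci = search$n_loci, method = "Nelder-Mead",
                 control = list(maxit = search$maxit))
    coarse[[r]] <- list(par = opt$par, convergence = opt$convergence)
  }
  # selection: score all coarse optima (and raw warm starts) under one
  # shared mid-size evaluation, then polish only the best few
  warm_x <- lapply(inits %||% list(), params_to_x, model = model,
                   search = search, free = free)
  cand <- c(lapply(coarse, `[[`, "par"), warm_x)
  select_seed <- sample.int(.Machine$integer.max, 1)
  scores <- vapply(cand, function(x)
    -objective(x, select_seed, search$polish_n_loci), 0)
  top <- order(scores, decreasing = TRUE)[
    seq_len(min(search$n_polish, length(cand)))]
  results <- list()
  for (r in top) {
    opt <- optim(cand[[r]], objective, crn_seed = restart_seeds[
                   (r - 1L) %% n_starts + 1L, 2],
                 n_loci = search$polish_n_loci, method = "Nelder-Mead",
                 control = list(maxit = search$polish_maxit))
    xc <- pmin(pmax(opt$par, lo), hi)
    params <- transform_to_params(xc, model, free, fixed)
    results[[length(results) + 1L]] <- list(
      params = params, x = xc, logCL_search = -opt$value,
      logCL_final = final_eval(params),
      convergence = opt$convergence)
  }
  # warm starts are also kept as zero-iteration candidates, so a model can
  # never rank below a nested model whose optimum it was seeded with
  for (x0 in warm_x) {
    xc <- pmin(pmax(x0, lo), hi)
    params <- transform_to_params(xc, model, free, fixed)
    results[[length(results) + 1L]] <- list(
      params = params, x = xc, logCL_search = NA_real_,
      logCL_final = final_eval(params), convergence = NA_integer_)
  }
  # refinement: short simplexes run directly on the shared final-evaluation
  # surface, from the best candidate overall and (if different) from the
  # best warm start, so a donated optimum from a nested model is always
  # given the chance to exploit the extra parameters
  if (search$refine_maxit > 0 && length(results)) {
    score <- vapply(results, function(z) z$logCL_final, 0)
    todo <- which.max(score)
    if (length(warm_x)) {
      w_idx <- length(results) - length(warm_x) + seq_along(warm_x)
      bw <- w_idx[which.max(score[w_idx])]
      todo <- unique(c(todo, bw))
    }
    for (ti in todo) {
      opt <- optim(results[[ti]]$x, objective, crn_seed = eval_seed,
                   n_loci = search$final_n_loci, method = "Nelder-Mead",
                   control = list(maxit = search$refine_maxit))
      xc <- pmin(pmax(opt$par, lo), hi)
      params <- transform_to_params(xc, model, free, fixed)
      results[[length(results) + 1L]] <- list(
        params = params, x = xc, logCL_search = -opt$value,
        logCL_final = final_eval(params), convergence = opt$convergence)
    }
  }
  finals <- vapply(results, function(z) z$logCL_final, 0)
  if (all(!is.finite(finals)))
    stop("no restart converged; search log attached",
         call. = FALSE)
  best <- results[[which.max(finals)]]
  logCL10 <- best$logCL_final
  k_eff <- length(free)
  aic <- 2 * k_eff - 2 * log(10) * logCL10
  structure(list(model = model, params = best$params, logCL10 = logCL10,
                 AIC = aic, fixed = fixed, free = free, k = k_eff,
                 restarts = tibble::tibble(
                   restart = seq_along(results),
                   logCL_search = vapply(results, function(z) z$logCL_search, 0),
                   logCL_final = finals,
                   convergence = vapply(results, function(z) z$convergence, 0L)),
                 obs_total = sfs_total(obs), obs_checksum = sfs_checksum(obs),
                 projection = proj, search = search, eval_seed = eval_seed),
            class = "demog_fit")
}

#' @export
print.demog_fit <- function(x, ...) {
  cat(sprintf("<demog_fit> %s: logCL10 = %.3f, AIC = %.3f\n",
              x$model$name, x$logCL10, x$AIC))
  print(unlist(x$params)[x$model$free])
  invisible(x)
}

#' @rdname fit_model
#' @param x a `demog_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.demog_fit <- function(x, ...) {
  p <- unlist(unclass(x$params))
  tibble::tibble(parameter = names(p), estimate = unname(p),
                 free = names(p) %in% x$free)
}

#' @rdname fit_model
#' @exportS3Method generics::glance
#' @export
glance.demog_fit <- function(x, ...) {
  tibble::tibble(model = x$model$name, k = x$k %||% x$model$k,
                 logCL10 = x$logCL10, AIC = x$AIC,
                 n_restarts = nrow(x$restarts))
}

#' Fit the full model ladder with warm starts
#'
#' Fits the requested models in order of increasing complexity, feeding each
#' model's optimum forward as an extra (warm) starting point for the models
#' that extend it: IM starts from SI plus weak migration, AM/SC from IM, and
#' SCS from SC and AM. All fits share one final-evaluation seed so their
#' AICs are comparable.
#'
#' @param obs observed [joint_sfs()] of counts.
#' @param models character vector of model names (see [model_spec()]).
#' @param search a [search_config()].
#' @param eval_seed shared final-evaluation seed; drawn if `NULL`.
#' @return named list of `demog_fit` objects.
#' @export
fit_all_models <- function(obs, models = c("SI", "IM", "AM", "SC", "SCS"),
                           search = search_config(), eval_seed = NULL,
                           fixed = list()) {
  if (is.null(eval_seed)) eval_seed <- sample.int(.Machine$integer.max, 1)
  order_all <- c("SI", "IM", "AM", "SC", "SCS")
  models <- order_all[order_all %in% models]
  fits <- list()
  with_mig <- function(p, mmj, mjm, T_1 = NA, T_2 = NA) {
    demographic_params(p$N_anc, p$N_pma, p$N_pja, p$T_S, T_1, T_2, mmj, mjm)
  }
  # gene flow masks divergence, so the true split can be much older than
  # the SI estimate suggests: every migration model also gets "deep split,
  # strong contact" starting shapes built from the SI optimum
  deep <- function(p_si, m, frac1) {
    demographic_params(p_si$N_anc, p_si$N_pma, p_si$N_pja, 10 * p_si$T_S,
                       frac1 * 10 * p_si$T_S, 0.01 * frac1 * 10 * p_si$T_S,
                       m, m)
  }
  warm <- function(name) {
    w <- list()
    p_si <- if (!is.null(fits$SI)) fits$SI$params
    p_im <- if (!is.null(fits$IM)) fits$IM$params
    if (name == "IM" && !is.null(p_si))
      w <- list(with_mig(p_si, 1e-4, 1e-4), with_mig(p_si, 1e-2, 1e-2))
    if (name %in% c("AM", "SC")) {
      base <- p_im %||% p_si
      if (!is.null(base)) {
        mmj <- max(base$mmj, 1e-3); mjm <- max(base$mjm, 1e-3)
        w <- list(with_mig(base, mmj, mjm, T_1 = 0.5 * base$T_S),
                  with_mig(base, mmj, mjm, T_1 = 0.1 * base$T_S))
      }
      if (name == "SC" && !is.null(p_si))
        w <- c(w, list(deep(p_si, 0.03, 0.1), deep(p_si, 0.003, 0.1)))
    }
    if (name == "SCS") {
      for (b in Filter(Negate(is.null), list(fits$SC$params, fits$AM$params))) {
        w <- c(w, list(with_mig(b, max(b$mmj, 1e-3), max(b$mjm, 1e-3),
                                T_1 = b$T_1, T_2 = 1e-3 * b$T_1),
                       with_mig(b, max(b$mmj, 1e-3), max(b$mjm, 1e-3),
                                T_1 = b$T_1, T_2 = 0.1 * b$T_1)))
      }
      if (!is.null(p_si))
        w <- c(w, list(deep(p_si, 0.03, 0.1)))
    }
    w
  }
  for (m in models)
    fits[[m]] <- fit_model(obs, model_spec(m), search, eval_seed = eval_seed,
                           inits = warm(m),
                           fixed = fixed[names(fixed) %in% MODEL_FREE[[m]]])
  fits
}

#' Rank fitted models by AIC
#'
#' AIC = `2k - 2 ln(10) logCL10` per fit; all fits must be on the same
#' observed SFS.
#'
#' @param fits list of `demog_fit` objects.
#' @return a `demog_comparison` tibble (model, k, logCL10, AIC, delta_AIC),
#'   ascending in AIC, with the best model name in `attr(, "best")`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2)
  cks <- vapply(fits, function(f) f$obs_checksum, 0)
  if (max(cks) - min(cks) > 1e-6 * max(abs(cks), 1))
    stop("fits were made on different observed spectra", call. = FALSE)
  tab <- dplyr::arrange(dplyr::bind_rows(lapply(fits, glance)), .data$AIC)
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tab <- tab[, c("model", "k", "logCL10", "AIC", "delta_AIC")]
  attr(tab, "best") <- tab$model[1]
  class(tab) <- c("demog_comparison", class(tab))
  tab
}

#' Parametric-bootstrap confidence intervals for a fitted model
#'
#' Simulates `n_boot` SFS of the observed total size from the fitted model's
#' expected proportions (multinomial over unmasked entries), refits the same
#' model to each, and reports 2.5/97.5 empirical percentiles per free
#' parameter.
#'
#' @param fit a `demog_fit`.
#' @param obs_S total site mass to resimulate; defaults to the fitted
#'   observed total.
#' @param n_boot bootstrap replicates (>= 2).
#' @param search [search_config()] for the refits (typically lighter than
#'   the original search).
#' @return tibble (parameter, estimate, lower, upper, n_boot_ok); failed
#'   refits are skipped with a warning, more than 20% failures is an error.
#' @export
bootstrap_ci <- function(fit, obs_S = NULL, n_boot = 100,
                         search = search_config(n_restarts = 2)) {
  stopifnot(n_boot >= 2)
  obs_S <- obs_S %||% fit$obs_total
  proj <- fit$projection
  exp_seed <- sample.int(.Machine$integer.max, 1)
  set.seed(exp_seed)
  e <- expected_sfs(fit$params, fit$model, proj,
                    n_loci = fit$search$final_n_loci)
  um <- unmasked_entries(dim(e$counts))
  probs <- e$counts[um]
  draws <- rmultinom(n_boot, round(obs_S), probs)
  ests <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    cnt <- matrix(0, nrow(e$counts), ncol(e$counts))
    cnt[um] <- draws[, b]
    bobs <- joint_sfs(cnt, proj)
    ests[[b]] <- tryCatch({
      bf <- fit_model(bobs, fit$model, search = search,
                      inits = list(fit$params), fixed = fit$fixed %||% list())
      unlist(unclass(bf$params))[fit$free %||% fit$model$free]
    }, error = function(e) NULL)
  }
  ok <- !vapply(ests, is.null, TRUE)
  if (mean(!ok) > 0.2)
    stop("more than 20% of bootstrap refits failed", call. = FALSE)
  if (any(!ok)) warning(sum(!ok), " bootstrap refit(s) failed and were skipped")
  m <- do.call(rbind, ests[ok])
  free <- fit$free %||% fit$model$free
  est <- unlist(unclass(fit$params))[free]
  tibble::tibble(
    parameter = free,
    estimate = unname(est),
    lower = apply(m, 2, quantile, 0.025, type = 1, names = FALSE),
    upper = apply(m, 2, quantile, 0.975, type = 1, names = FALSE),
    n_boot_ok = sum(ok)
  )
}
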