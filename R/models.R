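#' Demographic parameters for the two-deme divergence models
#'
#' Sizes are diploid effective sizes; times are generations before present;
#' `mmj` and `mjm` are per-generation migration proportions. Following the
#' coalescent (backward-in-time) convention, `mmj` — gene flow from deme A
#' ("maximus") into deme B ("jacobaeus") forward in time — is applied as the
#' probability that a lineage currently in deme B traces its ancestry into
#' deme A, and vice versa for `mjm`.
#'
#' @param N_anc,N_pma,N_pja diploid effective sizes (> 0): ancestral, deme A,
#'   deme B.
#' @param T_S split time (generations). At `T_S` the two demes merge into the
#'   ancestral deme (looking backward).
#' @param T_1,T_2 epoch boundaries used by the AM/SC/SCS models; must satisfy
#'   `0 <= T_2 <= T_1 <= T_S` where defined.
#' @param mmj,mjm migration proportions in `[0, 1)`.
#' @return a `demographic_params` list.
#' @export
demographic_params <- function(N_anc, N_pma, N_pja, T_S,
                               T_1 = NA_real_, T_2 = NA_real_,
                               mmj = 0, mjm = 0) {
  p <- list(N_anc = N_anc, N_pma = N_pma, N_pja = N_pja,
            T_S = T_S, T_1 = T_1, T_2 = T_2, mmj = mmj, mjm = mjm)
  for (nm in c("N_anc", "N_pma", "N_pja"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(nm, " must be a positive finite size", call. = FALSE)
  if (!is.finite(p$T_S) || p$T_S < 0) stop("T_S must be >= 0", call. = FALSE)
  ts <- c(p$T_2, p$T_1, p$T_S)
  ts <- ts[!is.na(ts)]
  if (any(diff(ts) < 0))
    stop("epoch times must satisfy 0 <= T_2 <= T_1 <= T_S", call. = FALSE)
  for (nm in c("mmj", "mjm"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] >= 1)
      stop(nm, " must lie in [0, 1)", call. = FALSE)
  structure(p, class = "demographic_params")
}

#' @export
print.demographic_params <- function(x, ...) {
  cat("<demographic_params>\n")
  print(unlist(x))
  invisible(x)
}

MODEL_FREE <- list(
  SI  = c("N_anc", "N_pma", "N_pja", "T_S"),
  IM  = c("N_anc", "N_pma", "N_pja", "T_S", "mmj", "mjm"),
  AM  = c("N_anc", "N_pma", "N_pja", "T_S", "T_1", "mmj", "mjm"),
  SC  = c("N_anc", "N_pma", "N_pja", "T_S", "T_1", "mmj", "mjm"),
  SCS = c("N_anc", "N_pma", "N_pja", "T_S", "T_1", "T_2", "mmj", "mjm")
)

#' Divergence/gene-flow model specification
#'
#' Five classical two-population speciation scenarios, distinguished by when
#' (backward in time) lineage migration between the demes is active:
#' * `SI`  strict isolation — never;
#' * `IM`  isolation with migration — from the present back to the split;
#' * `AM`  ancient migration — only between `T_1` and the split;
#' * `SC`  secondary contact — only between the present and `T_1`;
#' * `SCS` secondary contact with a recent stop — only between `T_2` and `T_1`.
#'
#' @param name one of `"SI"`, `"IM"`, `"AM"`, `"SC"`, `"SCS"`.
#' @return a `model_spec` with elements `name`, `free` (free parameter
#'   names) and `k` (their number).
#' @export
model_spec <- function(name = c("SI", "IM", "AM", "SC", "SCS")) {
  name <- match.arg(name)
  structure(list(name = name, free = MODEL_FREE[[name]],
                 k = length(MODEL_FREE[[name]])),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (k = %d): %s\n", x$name, x$k,
              paste(x$free, collapse = ", ")))
  invisible(x)
}

# migration epoch [lo, hi) for a model; errors if the model needs an epoch
# parameter the params do not define
migration_epoch <- function(params, model) {
  need <- setdiff(model$free, names(Filter(Negate(is.na), unclass(params))))
  if (length(need))
    stop("model ", model$name, " needs parameter(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  switch(model$name,
    SI  = c(0, 0),
    IM  = c(0, params$T_S),
    AM  = c(params$T_1, params$T_S),
    SC  = c(0, params$T_1),
    SCS = c(params$T_2, params$T_1)
  )
}

#' Preset secondary-contact-with-stop truth for a Pecten-like study
#'
#' Epoch times follow published point estimates for the *Pecten
#' maximus*/*P. jacobaeus* divergence (split 299,001 generations ago,
#' secondary contact 14,799 generations ago, gene flow ceasing 58
#' generations ago, stronger flow from the Mediterranean lineage into the
#' Atlantic one). Effective sizes and migration magnitudes are this
#' package's own order-of-magnitude choices (see the methods vignette).
#'
#' @return a [demographic_params()] object.
#' @export
pecten_scs_truth <- function() {
  demographic_params(N_anc = 50000, N_pma = 100000, N_pja = 20000,
                     T_S = 299001, T_1 = 14799, T_2 = 58,
                     mmj = 1e-5, mjm = 5e-5)
}
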