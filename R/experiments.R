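#' Printed experiment configurations
#'
#' Returns the parameter set (and matching domain/protocol) for the named
#' configuration of the published experiments:
#'
#' * `fig3a`/`fig3b`/`fig3c`: the time-series configurations for the naked,
#'   pseudo-protocell and true-protocell systems (the naked system uses
#'   `n_grid = 20`, `p_mv = 5e-4`, `t_apb = 0`, `f_bo = 1`).
#' * `fig5_naked`/`fig5_pseudo`/`fig5_true`: the common parameter lists for
#'   the spreading-chance sweeps (`p_at = 0.3`, `p_cd = 0.5`, `p_cf = 1e-4`,
#'   `p_mc = 0.05`, `p_mv = 0.5`, `p_nde = 5e-5`, `p_npp = 0.1`; naked again
#'   with `n_grid = 20`, `p_mv = 1e-3`, `t_apb = 0`, `f_bo = 1`).
#' * `fig7a`/`fig7b`/`fig7c`: as fig3 but the control species is a selfish
#'   parasite with an elevated template-conversion probability
#'   (`p_rtt = 0.9` vs the default 0.5).
#' * `fig8a`/`fig8b`/`fig8c`: the larger-scale system (20-nt domain with
#'   8-bp stems, `t_npb = 1.6e5`, and the caption's overrides).
#'
#' Scale constants never printed for the small protocell systems (`n_grid`,
#' `t_apb`, `l_am`, `f_op`, `f_bo`) use the package defaults; see the methods
#' vignette.
#'
#' @param name configuration name.
#' @param ... further parameter overrides applied on top.
#' @return A list with elements `params`, `spec` and `protocol`, class
#'   `rw_variant`.
#' @export
#' @examples
#' v <- rw_variant("fig3a")
#' v$params$p_mv
rw_variant <- function(name, ...) {
  name <- match.arg(name, c(
    "fig3a", "fig3b", "fig3c", "fig5_naked", "fig5_pseudo", "fig5_true",
    "fig7a", "fig7b", "fig7c", "fig8a", "fig8b", "fig8c"))
  naked <- list(n_grid = 20L, t_apb = 0, f_bo = 1)
  fig5 <- list(p_at = 0.3, p_cd = 0.5, p_cf = 1e-4, p_mc = 0.05, p_mv = 0.5,
               p_nde = 5e-5, p_npp = 0.1)
  fig8 <- list(t_npb = 1.6e5, p_nde = 5e-5, p_at = 0.3, p_fp = 5e-3,
               p_flr = 0.05)
  fig8_cell <- c(fig8, list(l_am = 600, p_mv = 0.5, p_adm = 5e-5,
                            p_alm = 5e-5, p_npp = 0.1, p_app = 0.2,
                            p_cb = 5e-6, p_cf = 1e-4, p_cd = 0.01,
                            p_mc = 0.05, f_si = 2, t_apb = 8e4))
  ctrl_parasite <- list(class_overrides = list(CONTROL = list(p_rtt = 0.9)))
  merge <- function(...) Reduce(utils::modifyList, list(...))
  ov <- switch(name,
    fig3a = merge(naked, list(p_mv = 5e-4, stage = "naked")),
    fig3b = list(stage = "pseudo_protocell"),
    fig3c = list(stage = "true_protocell"),
    fig5_naked = merge(fig5, naked, list(p_mv = 1e-3, stage = "naked")),
    fig5_pseudo = merge(fig5, list(stage = "pseudo_protocell")),
    fig5_true = merge(fig5, list(stage = "true_protocell")),
    fig7a = merge(naked, list(p_mv = 5e-4, stage = "naked"), ctrl_parasite),
    fig7b = merge(list(stage = "pseudo_protocell"), ctrl_parasite),
    fig7c = merge(list(stage = "true_protocell"), ctrl_parasite),
    fig8a = merge(fig8, naked, list(p_mv = 5e-4, stage = "naked")),
    fig8b = merge(fig8_cell, list(stage = "pseudo_protocell")),
    fig8c = merge(fig8_cell, list(stage = "true_protocell"))
  )
  ov <- utils::modifyList(ov, rlang::list2(...))
  params <- do.call(rw_params, ov)
  spec <- if (grepl("^fig8", name)) domain_spec(stem_len = 8) else domain_spec()
  stage <- params$stage
  structure(list(params = params, spec = spec,
                 protocol = rw_protocol_timeseries(stage)),
            class = c("rw_variant", "list"))
}

#' Inoculation protocols
#'
#' `rw_protocol()` builds a schedule tibble from explicit events;
#' `rw_protocol_timeseries()` is the published time-series schedule: for the
#' naked stage, 10 random rooms each receive 5 free copies of Rep, Nsr and
#' the control at step 1e4; for the protocell stages, 10 random rooms each
#' receive an empty protocell at step 1e3, and 10 random rooms each receive
#' a protocell containing 5 copies of each ribozyme (Rep+Nsr, plus Asr for
#' the true-protocell stage) and the control at step 1e4.
#'
#' @param step,rooms,species,copies,wrapped vectors defining one event per
#'   element (`species` is a list of character vectors).
#' @param stage simulation stage.
#' @param at_empty,at_ribozymes inoculation steps.
#' @param rooms_n,copies_n rooms and per-species copies per event.
#' @return A protocol tibble with columns
#'   `step, rooms, species, copies, wrapped`.
#' @export
rw_protocol <- function(step, rooms, species, copies, wrapped) {
  stopifnot(!is.unsorted(step), all(rooms > 0), all(copies >= 0))
  tibble::tibble(step = step, rooms = rooms, species = species,
                 copies = copies, wrapped = wrapped)
}

#' @rdname rw_protocol
#' @export
rw_protocol_timeseries <- function(stage, at_empty = 1e3, at_ribozymes = 1e4,
                                   rooms_n = 10, copies_n = 5) {
  stage <- match.arg(stage, STAGES)
  ribo <- switch(stage,
    naked = c("REP", "NSR", "CONTROL"),
    pseudo_protocell = c("REP", "NSR", "CONTROL"),
    true_protocell = c("REP", "NSR", "ASR", "CONTROL"))
  if (stage == "naked") {
    rw_protocol(at_ribozymes, rooms_n, list(ribo), copies_n, FALSE)
  } else {
    rw_protocol(c(at_empty, at_ribozymes), c(rooms_n, rooms_n),
                list(character(), ribo), c(0, copies_n), c(TRUE, TRUE))
  }
}

#' Has a species spread?
#'
#' A species counts as "spreading" in a run when its copy number strictly
#' exceeds the inoculum size (`spread_threshold`, default 50) at the check
#' step (`spread_check_step`).  Both are configurable so desk-scale runs can
#' check earlier horizons.
#'
#' @param trajectory an `rw_trajectory` or its census tibble.
#' @param species one of `rep`, `nsr`, `asr`, `control` (census column).
#' @param threshold copy-number threshold (strict).
#' @param check_step step at which to check; the trajectory must cover it.
#' @return Logical.
#' @export
spread_detected <- function(trajectory, species,
                            threshold = 50, check_step = NULL) {
  census <- if (inherits(trajectory, "rw_trajectory")) trajectory$census else trajectory
  species <- match.arg(species, c("rep", "nsr", "asr", "control"))
  if (is.null(check_step)) check_step <- max(census$step)
  if (max(census$step) < check_step) {
    abort("trajectory does not cover the spread check step")
  }
  at <- census[census$step <= check_step, , drop = FALSE]
  at <- at[which.max(at$step), ]
  at[[species]] > threshold
}

#' Spreading-chance parameter sweep
#'
#' For each value of the swept parameter, runs `n_reps` independently seeded
#' full protocols (seeds 1..n_reps by default) and counts per-species
#' spreading cases — runs in which the species exceeds the inoculum at the
#' check step — plus the co-spread counts (all of Rep, Nsr, Asr; Rep and
#' Asr).  All other parameters stay fixed at `base`.
#'
#' @param base an [rw_params()] set (e.g. `rw_variant("fig5_naked")$params`).
#' @param parameter name of the parameter to vary.
#' @param values numeric vector of values.
#' @param n_reps replicate runs per value.
#' @param seeds integer seeds (distinct), one per replicate.
#' @param horizon,check_step,threshold run length and spread criterion
#'   (default: the parameter set's `step_horizon`, `spread_check_step`,
#'   `spread_threshold`).
#' @param spec,protocol domain spec and inoculation protocol.
#' @return An `rw_sweep` tibble: one row per parameter value with
#'   per-species spreading-case counts out of `n_reps`.
#' @export
run_sweep <- function(base, parameter, values, n_reps = 100,
                      seeds = seq_len(n_reps), horizon = NULL,
                      check_step = NULL, threshold = NULL,
                      spec = domain_spec(),
                      protocol = rw_protocol_timeseries(base$stage)) {
  stopifnot(inherits(base, "rw_params"))
  if (!parameter %in% c(PROB_KEYS, SCALE_KEYS)) {
    abort(paste0("unknown sweep parameter: ", parameter))
  }
  if (anyDuplicated(seeds) > 0) abort("seeds must be distinct")
  stopifnot(length(seeds) == n_reps)
  if (is.null(check_step)) check_step <- base$spread_check_step
  if (is.null(horizon)) horizon <- check_step
  if (is.null(threshold)) threshold <- base$spread_threshold
  rows <- purrr::map_dfr(values, function(v) {
    ov <- stats::setNames(list(v), parameter)
    p <- do.call(rw_params, c(ov, list(base = unclass(base))))
    hits <- purrr::map(seeds, function(s) {
      traj <- rw_simulate(p, protocol = protocol, seed = s,
                          horizon = horizon, census_every = horizon,
                          spec = spec)
      c(rep = spread_detected(traj, "rep", threshold, check_step),
        nsr = spread_detected(traj, "nsr", threshold, check_step),
        asr = spread_detected(traj, "asr", threshold, check_step),
        control = spread_detected(traj, "control", threshold, check_step))
    })
    h <- do.call(rbind, hits)
    tibble::tibble(
      parameter = parameter, value = v, n_reps = n_reps,
      rep = sum(h[, "rep"]), nsr = sum(h[, "nsr"]), asr = sum(h[, "asr"]),
      control = sum(h[, "control"]),
      co_rep_nsr_asr = sum(h[, "rep"] & h[, "nsr"] & h[, "asr"]),
      co_rep_asr = sum(h[, "rep"] & h[, "asr"]))
  })
  class(rows) <- c("rw_sweep", class(rows))
  rows
}

#' Gene-loss probability at protocell division
#'
#' When a protocell carrying `k` copies of each of `n_types` ribozyme types
#' divides, every molecule is assigned to an offspring independently with
#' probability 1/2.  `gene_loss_prob()` is the closed-form probability that
#' some offspring lacks at least one type present in the parent,
#' `1 - (1 - 2^(1-k))^n_types`; `gene_loss_enumerate()` computes the same
#' probability by exhaustive enumeration of all `2^(k*n_types)` assignments.
#'
#' @param k copies per type.
#' @param n_types number of ribozyme types.
#' @return A probability.
#' @export
#' @examples
#' gene_loss_prob(2)        # 3/4
#' gene_loss_enumerate(2)   # identical
gene_loss_prob <- function(k, n_types = 2) {
  stopifnot(k >= 1, n_types >= 1)
  1 - (1 - 2^(1 - k))^n_types
}

#' @rdname gene_loss_prob
#' @export
gene_loss_enumerate <- function(k, n_types = 2) {
  stopifnot(k >= 1, n_types >= 1, k * n_types <= 20)
  n <- k * n_types
  type <- rep(seq_len(n_types), each = k)
  loss <- 0L
  for (mask in 0:(2^n - 1)) {
    side <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L)
    ok <- all(vapply(seq_len(n_types), function(t) {
      s <- side[type == t]
      any(s == 1) && any(s == 0)
    }, logical(1)))
    if (!ok) loss <- loss + 1L
  }
  loss / 2^n
}
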