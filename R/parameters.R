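#' @useDynLib ribocell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort .data
#' @import tibble
NULL

# The 29 per-step event probabilities of the model, by lower-cased symbol.
PROB_KEYS <- c(
  "p_ad", "p_adm", "p_af", "p_afr", "p_ajm", "p_alm", "p_app", "p_at", "p_bb",
  "p_cb", "p_cd", "p_cf", "p_flr", "p_fp", "p_mc", "p_mf", "p_mv", "p_nd",
  "p_nde", "p_nf", "p_nfr", "p_npp", "p_rb", "p_rd", "p_rl", "p_rtt", "p_sp",
  "p_tl", "p_tlr"
)

SCALE_KEYS <- c("n_grid", "t_npb", "t_apb", "l_am", "f_op", "f_si", "f_bo")

SWITCH_KEYS <- c(
  "stage", "step_horizon", "spread_threshold", "spread_check_step",
  "class_overrides", "refold", "outward_permeation", "outside_rna_moves",
  "membrane_form", "separation", "attraction"
)

STAGES <- c("naked", "pseudo_protocell", "true_protocell")
RNA_CLASSES <- c("REP", "NSR", "ASR", "CONTROL")

#' Build and validate a model parameter set
#'
#' Collects every per-step event probability of the model together with the
#' scale constants (grid side, initial totals, membrane lower limit, the
#' osmotic-pressure, inner-ion and outside-bond-breaking factors) into a
#' validated parameter set.  All probabilities are per Monte-Carlo step; no
#' physical units are attached.
#'
#' @param ... named overrides of any parameter key (e.g. `p_mv = 5e-4`,
#'   `n_grid = 20`).  Unknown keys are an error.
#' @param stage one of `"naked"`, `"pseudo_protocell"`, `"true_protocell"`.
#'   The naked stage requires `t_apb = 0` (no amphiphile chemistry); the
#'   pseudo-protocell stage disables Asr catalysis.
#' @param base optional list of starting values (defaults to
#'   [rw_default_params()]); overrides in `...` are applied on top.
#'
#' @return A named list of class `rw_params`.
#' @export
#' @examples
#' p <- rw_params(stage = "naked", n_grid = 20, p_mv = 5e-4, t_apb = 0, f_bo = 1)
#' p$p_at
rw_params <- function(..., stage = NULL, base = rw_default_params()) {
  raw <- utils::modifyList(base, rlang::list2(...))
  if (!is.null(stage)) raw$stage <- stage
  validate_parameters(raw)
}

#' Default parameter values
#'
#' The package's baseline configuration: the protocell-stage value set used by
#' the time-series experiments (see [rw_variant()] for the printed
#' configurations and their naked-stage overrides).
#'
#' @return A plain named list (not yet validated).
#' @export
rw_default_params <- function() {
  list(
    p_ad = 0.01, p_adm = 1e-4, p_af = 1e-3, p_afr = 0.9, p_ajm = 0.9,
    p_alm = 1e-4, p_app = 0.1, p_at = 0.2, p_bb = 1e-6, p_cb = 1e-5,
    p_cd = 0.1, p_cf = 5e-4, p_flr = 0.1, p_fp = 0.01, p_mc = 0.01,
    p_mf = 0.1, p_mv = 0.2, p_nd = 0.01, p_nde = 1e-4, p_nf = 2e-4,
    p_nfr = 0.9, p_npp = 0.01, p_rb = 0.9, p_rd = 0.9, p_rl = 1e-6,
    p_rtt = 0.5, p_sp = 0.5, p_tl = 2e-4, p_tlr = 0.9,
    n_grid = 30, t_npb = 8e4, t_apb = 4e4, l_am = 100,
    f_op = 1, f_si = 2, f_bo = 10,
    stage = "true_protocell",
    step_horizon = 5e5, spread_threshold = 50, spread_check_step = 5e5,
    class_overrides = list(),
    refold = TRUE, outward_permeation = TRUE, outside_rna_moves = FALSE,
    membrane_form = "saturating", separation = "processive",
    attraction = "flux"
  )
}

#' Validate a raw key/value map into a parameter set
#'
#' Checks that every required key is present, every probability lies in
#' \[0, 1\], the scale constants satisfy their bounds (`n_grid >= 1`,
#' `l_am >= 2`, `f_bo >= 1`, non-negative totals and factors), the stage is
#' consistent with the amphiphile settings, and no unknown keys are present.
#'
#' @param raw a named list of parameter values.
#' @return The validated list with class `rw_params`.
#' @export
validate_parameters <- function(raw) {
  stopifnot(is.list(raw))
  known <- c(PROB_KEYS, SCALE_KEYS, SWITCH_KEYS)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter key(s): ", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(c(PROB_KEYS, SCALE_KEYS, "stage"), names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing parameter key(s): ", paste(missing, collapse = ", ")))
  }
  for (k in PROB_KEYS) {
    v <- raw[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("probability out of range: ", k))
    }
  }
  num1 <- function(k, lo) {
    v <- raw[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo) {
      abort(paste0("parameter out of range: ", k, " (must be >= ", lo, ")"))
    }
    v
  }
  raw$n_grid <- as.integer(num1("n_grid", 1))
  raw$t_npb <- num1("t_npb", 0)
  raw$t_apb <- num1("t_apb", 0)
  raw$l_am <- num1("l_am", 2)
  num1("f_op", 0); num1("f_si", 0); num1("f_bo", 1)
  if (!is.character(raw$stage) || length(raw$stage) != 1 ||
      !raw$stage %in% STAGES) {
    abort("stage must be one of naked, pseudo_protocell, true_protocell")
  }
  if (raw$stage == "naked" && raw$t_apb > 0) {
    abort("naked stage requires t_apb = 0 (no amphiphile chemistry)")
  }
  if (is.null(raw$step_horizon)) raw$step_horizon <- 5e5
  num1("step_horizon", 0)
  if (is.null(raw$spread_threshold)) raw$spread_threshold <- 50
  if (is.null(raw$spread_check_step)) raw$spread_check_step <- 5e5
  if (is.null(raw$class_overrides)) raw$class_overrides <- list()
  ov <- raw$class_overrides
  if (!is.list(ov)) abort("class_overrides must be a list")
  if (length(ov) > 0) {
    bad <- setdiff(names(ov), RNA_CLASSES)
    if (length(bad) > 0) abort(paste0("class_overrides for unknown class: ", bad[1]))
    for (cl in names(ov)) {
      o <- ov[[cl]]
      if (!is.list(o) || length(setdiff(names(o), "p_rtt")) > 0) {
        abort("class_overrides support only p_rtt")
      }
      if (!is.null(o$p_rtt) && (o$p_rtt < 0 || o$p_rtt > 1)) {
        abort("probability out of range: class_overrides p_rtt")
      }
    }
  }
  for (k in c("refold", "outward_permeation", "outside_rna_moves")) {
    if (is.null(raw[[k]])) raw[[k]] <- if (k == "outside_rna_moves") FALSE else TRUE
    if (!is.logical(raw[[k]]) || length(raw[[k]]) != 1 || is.na(raw[[k]])) {
      abort(paste0(k, " must be TRUE or FALSE"))
    }
  }
  if (is.null(raw$membrane_form)) raw$membrane_form <- "saturating"
  if (!raw$membrane_form %in% c("saturating", "constant")) {
    abort("membrane_form must be 'saturating' or 'constant'")
  }
  if (is.null(raw$separation)) raw$separation <- "processive"
  if (!raw$separation %in% c("processive", "memoryless", "ratchet")) {
    abort("separation must be 'processive', 'memoryless' or 'ratchet'")
  }
  if (is.null(raw$attraction)) raw$attraction <- "flux"
  if (!raw$attraction %in% c("flux", "extension", "template", "site")) {
    abort("attraction must be 'flux', 'extension', 'template' or 'site'")
  }
  raw <- raw[known[known %in% names(raw)]]
  structure(raw, class = c("rw_params", "list"))
}

#' @export
print.rw_params <- function(x, ...) {
  cat("<rw_params> stage =", x$stage,
      "| grid", paste0(x$n_grid, "x", x$n_grid),
      "| T_NPB", x$t_npb, "| T_APB", x$t_apb, "| L_AM", x$l_am, "\n")
  probs <- unlist(x[PROB_KEYS])
  print(probs)
  invisible(x)
}

#' Serialize / read a parameter set (YAML)
#'
#' @param params an `rw_params` object.
#' @param path file path.
#' @return `rw_params_read()` returns the validated parameter set.
#' @export
rw_params_write <- function(params, path) {
  stopifnot(inherits(params, "rw_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname rw_params_write
#' @export
rw_params_read <- function(path) {
  validate_parameters(yaml::read_yaml(path))
}

# ---- derived per-event probabilities (closed forms) -------------------------

#' Derived event probabilities
#'
#' Closed-form per-step probabilities derived from the base parameters:
#'
#' * `rna_move_prob(p_mv, m)`: an RNA of mass `m` (in nucleotide units) moves
#'   with `p_mv / m^(1/3)` — heavier chains diffuse more slowly.
#' * `amphiphile_leave_prob(p_alm, f_op, n, b)`: a membrane amphiphile leaves
#'   with `p_alm / (1 + f_op * n / (b/2)^(3/2))`; `n` is the interior
#'   impermeable content (nucleotide residues), `b` the membrane amphiphile
#'   count, `(b/2)^(3/2)` a scale for the cellular volume.  More interior RNA
#'   means a more swollen cell and a lower leave rate (the osmotic-pressure
#'   effect).
#' * `permeation_probs(p_npp, p_app, f_si, n, b, l_am)`: per-molecule inward
#'   crossing probabilities for nucleotide precursors,
#'   `(1 - (1-p_npp) * (l_am/b)^(3/2)) / (1 + f_si * n / (b/2)^(3/2))`, and
#'   amphiphile precursors, `1 - (1-p_app) * (l_am/b)^(3/2)`.
#' * `division_prob(p_cd, l_am, b)`: `max(0, p_cd * (1 - 2*l_am/b))` — a cell
#'   thinner than two minimal membranes cannot produce two viable offspring.
#' * `membrane_form_prob(p_mf, a, l_am)`: 0 below the assembly threshold
#'   `l_am`, otherwise `p_mf * (1 - l_am/(a+1))` (`form = "saturating"`,
#'   default) or flat `p_mf` (`form = "constant"`).
#'
#' @param p_mv,p_alm,p_npp,p_app,p_cd,p_mf base per-step probabilities.
#' @param m RNA mass in nucleotide units (>= 1).
#' @param f_op,f_si osmotic-pressure and inner-ion factors (>= 0).
#' @param n interior impermeable units (nucleotide residues, >= 0).
#' @param b membrane amphiphile count.
#' @param l_am membrane lower limit (amphiphiles).
#' @param a free amphiphiles in the room.
#' @param form membrane-formation functional form.
#' @return A probability (or, for `permeation_probs()`, a named list with
#'   elements `np` and `ap`).
#' @name derived_probs
NULL

#' @rdname derived_probs
#' @export
rna_move_prob <- function(p_mv, m) {
  if (any(m < 1)) abort("RNA mass m must be >= 1")
  p_mv / m^(1 / 3)
}

#' @rdname derived_probs
#' @export
amphiphile_leave_prob <- function(p_alm, f_op, n, b) {
  if (any(b < 2)) abort("membrane amphiphile count b must be >= 2")
  if (any(n < 0)) abort("interior content n must be >= 0")
  p_alm / (1 + f_op * n / (b / 2)^(3 / 2))
}

#' @rdname derived_probs
#' @export
permeation_probs <- function(p_npp, p_app, f_si, n, b, l_am) {
  if (any(b < l_am)) abort("membrane amphiphile count b must be >= l_am")
  shrink <- (l_am / b)^(3 / 2)
  np <- (1 - (1 - p_npp) * shrink) / (1 + f_si * n / (b / 2)^(3 / 2))
  ap <- 1 - (1 - p_app) * shrink
  list(np = np, ap = ap)
}

#' @rdname derived_probs
#' @export
division_prob <- function(p_cd, l_am, b) {
  if (any(b < 2)) abort("membrane amphiphile count b must be >= 2")
  pmax(0, p_cd * (1 - 2 * l_am / b))
}

#' @rdname derived_probs
#' @export
membrane_form_prob <- function(p_mf, a, l_am, form = c("saturating", "constant")) {
  form <- match.arg(form)
  if (any(a < 0)) abort("free amphiphile count a must be >= 0")
  out <- ifelse(a < l_am, 0,
                if (form == "saturating") p_mf * (1 - l_am / (a + 1)) else p_mf)
  out
}
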