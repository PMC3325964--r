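#' Create a simulation
#'
#' Builds the toroidal `n_grid` x `n_grid` world, seeds the RNG, and
#' distributes the initial nucleotide-precursor (`t_npb`) and
#' amphiphile-precursor (`t_apb`) totals uniformly at random over the grid
#' rooms.  The returned handle has reference semantics: stepping functions
#' advance it in place.
#'
#' @param params an [rw_params()] parameter set.
#' @param spec a [domain_spec()] object.
#' @param seed integer RNG seed; every stochastic draw of the run flows from
#'   it, so equal seeds give bitwise-identical trajectories.
#' @return An object of class `rw_sim`.
#' @export
#' @examples
#' p <- rw_params(stage = "naked", n_grid = 5, t_npb = 100, t_apb = 0,
#'                f_bo = 1)
#' sim <- rw_sim(p, seed = 1)
#' rw_census(sim)
rw_sim <- function(params, spec = domain_spec(), seed = 1L) {
  stopifnot(inherits(params, "rw_params"), inherits(spec, "rw_domain"))
  set.seed(as.integer(seed))
  xp <- sim_new(unclass(params), spec$stem_len, lapply(spec$loops, seq_to_int))
  sim_initialize(xp)
  sim <- new.env(parent = emptyenv())
  sim$xp <- xp
  sim$params <- params
  sim$spec <- spec
  sim$seed <- as.integer(seed)
  sim$rng <- get(".Random.seed", globalenv())
  class(sim) <- "rw_sim"
  sim
}

# Each simulation owns its RNG stream: stochastic operations restore the
# handle's saved state, run, and save it back, so interleaved simulations
# stay independently reproducible.
with_sim_rng <- function(sim, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", sim$rng, globalenv())
  on.exit({
    sim$rng <- get(".Random.seed", globalenv())
    if (had) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  force(code)
}

#' @export
print.rw_sim <- function(x, ...) {
  info <- sim_info(x$xp)
  cat("<rw_sim>", x$params$stage, "stage,",
      paste0(info$n_grid, "x", info$n_grid), "grid, step", info$step,
      "-", info$n_strands, "strand records\n")
  invisible(x)
}

#' Advance a simulation
#'
#' Runs `steps` Monte-Carlo steps.  Each step executes the fixed phase order:
#' nucleotide turnover; amphiphile turnover; strand end-decay and bond
#' breakage; random ligation; template dynamics (unfolding/refolding, Rep
#' binding, substrate attraction, template-directed ligation, base-pair
#' separation and product release); membrane formation, exchange and
#' permeation; protocell break/fuse/divide; movement.  Conservation of
#' nucleotide and amphiphile units is audited after every step and any
#' violation is a hard error.
#'
#' @param sim an [rw_sim()] handle.
#' @param steps number of steps (>= 0).
#' @return The handle, invisibly (advanced in place).
#' @export
rw_advance <- function(sim, steps) {
  stopifnot(inherits(sim, "rw_sim"), steps >= 0)
  if (steps > 0) with_sim_rng(sim, sim_advance(sim$xp, as.integer(steps)))
  invisible(sim)
}

#' Update simulation parameters mid-run
#'
#' Replaces event probabilities of a running simulation (the grid size cannot
#' change).  Used for mid-run perturbations such as raising the molecular
#' movement rate after the ribozymes have spread.
#'
#' @param sim an [rw_sim()] handle.
#' @param ... parameter overrides, e.g. `p_mv = 0.01`.
#' @return The handle, invisibly.
#' @export
rw_set_params <- function(sim, ...) {
  new <- rw_params(..., base = unclass(sim$params))
  sim_set_param(sim$xp, unclass(new))
  sim$params <- new
  invisible(sim)
}

#' Census of the current state
#'
#' Counts every living strand by ribozyme class (a strand is counted once in
#' every class whose characteristic domain it carries; class-free strands are
#' `other_rna`), the free molecule and precursor totals, membrane amphiphiles,
#' and the protocell composition classes (all three ribozymes; Rep+Nsr only;
#' Rep+Asr only; Nsr+Asr only; single-ribozyme; none).  Substrates attached
#' to a template are not counted until released.
#'
#' @param sim an [rw_sim()] handle.
#' @return A one-row tibble; composition classes always partition
#'   `cells_total`.
#' @export
rw_census <- function(sim) {
  cs <- sim_census_cpp(sim$xp)
  tibble::as_tibble(c(list(step = sim_info(sim$xp)$step), cs))
}

#' Conservation audit
#'
#' Recomputes the global nucleotide-unit total (precursors + free nucleotides
#' + strand residues + attached-substrate residues) and amphiphile-unit total
#' (precursors + free + membrane amphiphiles) from scratch and compares them
#' with the conserved baselines (initial totals plus inoculated units).
#'
#' @param sim an [rw_sim()] handle.
#' @return A one-row tibble with observed and expected totals and `ok`.
#' @export
rw_audit <- function(sim) {
  tibble::as_tibble(sim_audit(sim$xp))
}

#' Inoculate molecules or protocells
#'
#' Adds ribozyme/control strands (optionally wrapped in protocells) or empty
#' protocells to randomly chosen rooms.  Each inoculated copy is the minimal
#' domain-length sequence for its species ([ribozyme_sequence()]).  The
#' nucleotide and amphiphile units added here shift the conservation
#' baselines accordingly.
#'
#' @param sim an [rw_sim()] handle.
#' @param rooms number of distinct rooms to inoculate.
#' @param species character vector of classes (`REP`, `NSR`, `ASR`,
#'   `CONTROL`); empty for empty-protocell inoculation.
#' @param copies copies of each species per room.
#' @param wrapped wrap each room's inoculum in a protocell.
#' @param membrane membrane amphiphile count of inoculated protocells
#'   (defaults to `l_am`).
#' @return The handle, invisibly.
#' @export
rw_inoculate <- function(sim, rooms, species = character(), copies = 5,
                         wrapped = FALSE, membrane = NULL) {
  stopifnot(inherits(sim, "rw_sim"))
  n_grid <- sim$params$n_grid
  dump <- sim_dump(sim$xp)
  with_sim_rng(sim, {
    if (wrapped || length(species) == 0) {
      free <- which(dump$cell < 0) - 1L
      if (length(free) < rooms) abort("not enough naked rooms to inoculate")
      target <- if (length(free) == 1) free else sample(free, rooms)
    } else {
      target <- sample.int(n_grid^2, rooms) - 1L
    }
    b <- if (is.null(membrane)) sim$params$l_am else membrane
    for (r in target) {
      if (wrapped || length(species) == 0) {
        sim_make_cell(sim$xp, r, b, TRUE)
      }
      for (sp in species) {
        code <- seq_to_int(ribozyme_sequence(sp, sim$spec))
        for (i in seq_len(copies)) sim_add_strand(sim$xp, r, code, TRUE)
      }
    }
  })
  invisible(sim)
}

#' Run a full experiment protocol
#'
#' Drives a simulation from step 0 to `horizon`, applying the inoculation
#' schedule of `protocol` at its configured steps and recording a census
#' every `census_every` steps (plus immediately after each inoculation).
#'
#' @param params an [rw_params()] set.
#' @param protocol a protocol tibble from [rw_protocol()] /
#'   [rw_protocol_timeseries()].
#' @param seed RNG seed.
#' @param horizon total number of Monte-Carlo steps.
#' @param census_every census cadence in steps.
#' @param spec a [domain_spec()].
#' @param keep_sim keep the (mutable) simulation handle on the result.
#' @return An object of class `rw_trajectory`: a list with the census tibble
#'   (`$census`), the parameter set, the protocol, and optionally the handle.
#' @export
rw_simulate <- function(params, protocol = rw_protocol_timeseries(params$stage),
                        seed = 1L, horizon = params$step_horizon,
                        census_every = 1000, spec = domain_spec(),
                        keep_sim = FALSE) {
  sim <- rw_sim(params, spec = spec, seed = seed)
  events <- protocol[order(protocol$step), , drop = FALSE]
  if (any(events$step > horizon)) {
    events <- events[events$step <= horizon, , drop = FALSE]
  }
  rows <- list(rw_census(sim))
  now <- 0
  next_census <- census_every
  apply_event <- function(e) {
    rw_inoculate(sim, rooms = e$rooms, species = e$species[[1]],
                 copies = e$copies, wrapped = e$wrapped)
  }
  ei <- 1
  while (now < horizon) {
    stop_at <- min(horizon, next_census,
                   if (ei <= nrow(events)) events$step[ei] else Inf)
    if (stop_at > now) {
      rw_advance(sim, stop_at - now)
      now <- stop_at
    }
    if (ei <= nrow(events) && now == events$step[ei]) {
      apply_event(events[ei, ])
      ei <- ei + 1
      rows[[length(rows) + 1]] <- rw_census(sim)
    }
    if (now == next_census) {
      rows[[length(rows) + 1]] <- rw_census(sim)
      next_census <- next_census + census_every
    }
  }
  out <- list(census = dplyr::distinct(dplyr::bind_rows(rows)),
              params = params, protocol = protocol, seed = seed,
              spec = spec)
  if (keep_sim) out$sim <- sim
  class(out) <- "rw_trajectory"
  out
}

#' @export
print.rw_trajectory <- function(x, ...) {
  cat("<rw_trajectory>", x$params$stage, "stage,",
      max(x$census$step), "steps,", nrow(x$census), "census records\n")
  last <- x$census[nrow(x$census), ]
  cat("  final counts: Rep", last$rep, "Nsr", last$nsr, "Asr", last$asr,
      "control", last$control, "| protocells", last$cells_total, "\n")
  invisible(x)
}

#' Per-room spatial snapshot
#'
#' One row per grid room with its coordinates, protocell occupancy, membrane
#' size, pool counts and per-class ribozyme counts — the layout used for
#' spatial-distribution figures.
#'
#' @param sim an [rw_sim()] handle (or an `rw_trajectory` kept with
#'   `keep_sim = TRUE`).
#' @param path optional CSV path; if given the snapshot is also written.
#' @return A tibble with `n_grid^2` rows.
#' @export
rw_snapshot <- function(sim, path = NULL) {
  if (inherits(sim, "rw_trajectory")) sim <- sim$sim
  out <- tibble::as_tibble(sim_snapshot_cpp(sim$xp))
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Export the strand pool as FASTA
#'
#' Writes every living strand as an RNA FASTA record; ids encode the room,
#' inside/outside-protocell location and the classified functions.
#'
#' @param sim an [rw_sim()] handle (or `rw_trajectory` with the handle kept).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
rw_write_fasta <- function(sim, path) {
  if (inherits(sim, "rw_trajectory")) sim <- sim$sim
  tab <- sim_strand_table(sim$xp)
  cls_name <- function(m) {
    hit <- RNA_CLASSES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0]
    if (length(hit) == 0) "OTHER" else paste(hit, collapse = "+")
  }
  ids <- sprintf("strand%04d|room=%d|%s|%s", seq_along(tab$seq), tab$room,
                 ifelse(tab$inside == 1, "inside", "outside"),
                 vapply(tab$cls, cls_name, ""))
  if (length(tab$seq) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  xs <- Biostrings::RNAStringSet(tab$seq)
  names(xs) <- ids
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}
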