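# Helpers for constructing small simulation states directly against the
# engine's test surface (sim_* entry points operate on the external pointer).

# a parameter set with every event switched off; individual probabilities are
# then enabled per test
params_off <- function(stage = "naked", n_grid = 3, ...) {
  zeros <- stats::setNames(as.list(rep(0, length(ribocell:::PROB_KEYS))),
                           ribocell:::PROB_KEYS)
  base <- utils::modifyList(rw_default_params(), zeros)
  base$stage <- stage
  base$n_grid <- n_grid
  base$t_npb <- 0
  base$t_apb <- 0
  base$l_am <- 10
  base$f_bo <- 1
  rw_params(..., base = base)
}

new_sim <- function(params, seed = 1, spec = domain_spec()) {
  rw_sim(params, spec = spec, seed = seed)
}

# direct engine accessors (internal surface)
ph <- function(sim, phase) ribocell:::sim_phase(sim$xp, phase)
dump_state <- function(sim) ribocell:::sim_dump(sim$xp)
set_pool <- function(sim, room, np = 0, nt = c(0, 0, 0, 0), ap = 0, am = 0) {
  ribocell:::sim_set_pool(sim$xp, room, np, as.integer(nt), ap, am)
}
add_strand <- function(sim, room, seq, folded = TRUE) {
  ribocell:::sim_add_strand(sim$xp, room, ribocell:::seq_to_int(seq), folded)
}
add_attachment <- function(sim, sid, start, seq, ok = NULL, paired = NULL) {
  code <- ribocell:::seq_to_int(seq)
  if (is.null(ok)) ok <- rep(1L, length(code))
  if (is.null(paired)) paired <- rep(1L, length(code))
  ribocell:::sim_add_attachment(sim$xp, sid, start, code,
                                as.integer(ok), as.integer(paired))
}
strand_info <- function(sim, sid) dump_state(sim)$strands[[sid + 1]]
strand_seq <- function(info) ribocell:::int_to_seq(info$seq)
pool_of <- function(sim, room) {
  d <- dump_state(sim)
  ci <- d$cell[room + 1]
  if (ci >= 0) {
    cl <- d$cells[[ci + 1]]
    list(np = cl$np, nt = cl$nt, ap = cl$ap, am = cl$am, b = cl$b)
  } else {
    list(np = d$np[room + 1], nt = d$nt[room + 1, ], ap = d$ap[room + 1],
         am = d$am[room + 1], b = 0)
  }
}

# brute-force window-scanning classification oracle (independent of the
# engine implementation)
classify_oracle <- function(seq, spec = domain_spec()) {
  n <- nchar(seq)
  dl <- spec$domain_len
  s <- spec$stem_len
  if (n >= 2 * dl || n < dl) return(character())
  ch <- strsplit(seq, "")[[1]]
  hits <- character()
  for (start in seq_len(n - dl + 1)) {
    w <- ch[start:(start + dl - 1)]
    loop <- paste(w[(s + 1):(s + 4)], collapse = "")
    stem_ok <- all(vapply(seq_len(s), function(i) {
      bases_pair(w[s + 1 - i], w[s + 4 + i], allow_wobble = TRUE)
    }, logical(1)))
    if (!stem_ok) next
    for (cl in names(spec$loops)) {
      if (identical(loop, unname(spec$loops[[cl]]))) hits <- c(hits, cl)
    }
  }
  sort(unique(hits))
}

random_rna <- function(len) {
  paste(sample(c("A", "U", "C", "G"), len, replace = TRUE), collapse = "")
}
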