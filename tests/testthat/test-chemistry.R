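# Event-level behaviour of the RNA chemistry, exercised by running single
# engine phases on hand-built states.
# Phase ids: 1 nucleotide turnover, 3 strand decay, 4 random ligation,
# 51 template state, 52 Rep bind/drop, 53 attraction, 54 template ligation,
# 55 separation/release.

as_template <- function(sim, sid) ribocell:::sim_set_template(sim$xp, sid, TRUE)

test_that("nucleotide turnover converts, decays and conserves units", {
  # certain formation empties the precursor pool into roughly equal bases
  sim <- new_sim(params_off(p_nf = 1), seed = 2)
  set_pool(sim, 0, np = 8000)
  ph(sim, 1)
  p <- pool_of(sim, 0)
  expect_equal(p$np, 0)
  expect_equal(sum(p$nt), 8000)
  expect_true(all(abs(p$nt - 2000) < 3 * sqrt(8000 * 0.25 * 0.75)))

  # decay returns nucleotides to precursors
  sim <- new_sim(params_off(p_nd = 1), seed = 3)
  set_pool(sim, 0, nt = c(10, 20, 30, 40))
  ph(sim, 1)
  p <- pool_of(sim, 0)
  expect_equal(p$np, 100)
  expect_equal(sum(p$nt), 0)

  # nothing happens at zero rates; units conserved either way
  sim <- new_sim(params_off(), seed = 4)
  set_pool(sim, 0, np = 50, nt = c(1, 2, 3, 4))
  before <- pool_of(sim, 0)
  ph(sim, 1)
  expect_identical(pool_of(sim, 0), before)
})

test_that("nucleotide synthesis is catalyzed only by a folded Nsr present", {
  p <- params_off(p_nf = 0, p_nfr = 1)
  # folded Nsr in the room: every precursor converts
  sim <- new_sim(p, seed = 5)
  set_pool(sim, 0, np = 50)
  add_strand(sim, 0, "AAAACUGUUU")
  ph(sim, 1)
  expect_equal(pool_of(sim, 0)$np, 0)

  # Nsr in a different room: no conversion
  sim <- new_sim(p, seed = 6)
  set_pool(sim, 0, np = 50)
  add_strand(sim, 5, "AAAACUGUUU")
  ph(sim, 1)
  expect_equal(pool_of(sim, 0)$np, 50)

  # an unfolded Nsr is non-functional
  sim <- new_sim(p, seed = 7)
  set_pool(sim, 0, np = 50)
  sid <- add_strand(sim, 0, "AAAACUGUUU")
  as_template(sim, sid)
  ph(sim, 1)
  expect_equal(pool_of(sim, 0)$np, 50)
})

test_that("strand decay trims ends, fragments chains and conserves residues", {
  # certain end decay trims both termini to precursors
  sim <- new_sim(params_off(p_nde = 1), seed = 8)
  sid <- add_strand(sim, 0, "AUCGGA")
  ph(sim, 3)
  expect_equal(strand_seq(strand_info(sim, sid)), "UCGG")
  expect_equal(pool_of(sim, 0)$np, 2)

  # certain bond breakage dissolves a 4-mer into free nucleotides
  sim <- new_sim(params_off(p_bb = 1), seed = 9)
  sid <- add_strand(sim, 0, "AUCG")
  ph(sim, 3)
  expect_false(strand_info(sim, sid)$alive)
  expect_equal(pool_of(sim, 0)$nt, c(1, 1, 1, 1))
  expect_true(rw_audit(sim)$ok)

  # templates engaged with substrates are protected
  sim <- new_sim(params_off(p_nde = 1, p_bb = 1), seed = 10)
  sid <- add_strand(sim, 0, "AAAAGUCUUU")
  add_attachment(sim, sid, 0, "U")
  ph(sim, 3)
  expect_true(strand_info(sim, sid)$alive)
  expect_equal(strand_seq(strand_info(sim, sid)), "AAAAGUCUUU")
})

test_that("random ligation joins free nucleotides and chain ends", {
  # exactly two free nucleotides must fuse into one dimer at rate 1
  sim <- new_sim(params_off(p_rl = 1), seed = 11)
  set_pool(sim, 0, nt = c(1, 1, 0, 0))
  ph(sim, 4)
  d <- dump_state(sim)
  expect_equal(sum(d$nt), 0)
  seqs <- strand_seq(strand_info(sim, 0))
  expect_true(seqs %in% c("AU", "UA"))

  # a lone nucleotide with a strand must extend the strand by one residue
  sim <- new_sim(params_off(p_rl = 1), seed = 12)
  set_pool(sim, 0, nt = c(0, 0, 1, 0))
  sid <- add_strand(sim, 0, "GGG")
  ph(sim, 4)
  expect_equal(nchar(strand_seq(strand_info(sim, sid))), 4)
  expect_equal(sum(dump_state(sim)$nt), 0)

  # dimer yield matches the binomial expectation at a low rate
  sim <- new_sim(params_off(p_rl = 1e-3, n_grid = 3), seed = 13)
  for (r in 0:8) set_pool(sim, r, nt = c(300, 300, 300, 300))
  ph(sim, 4)
  n_lig <- 9 * 1200 - sum(dump_state(sim)$nt)
  expected <- 9 * 1200 * 1e-3  # each success consumes two nucleotides
  expect_true(abs(n_lig / 2 - expected) < 3 * sqrt(expected))
})

test_that("folding state flips follow the template-conversion probability", {
  # certain unfolding, then certain refolding at the complementary rate
  sim <- new_sim(params_off(p_rtt = 1), seed = 14)
  sid <- add_strand(sim, 0, "AAAAGUCUUU")
  ph(sim, 51)
  expect_false(strand_info(sim, sid)$folded)

  sim <- new_sim(params_off(p_rtt = 0), seed = 15)
  sid <- add_strand(sim, 0, "AAAAGUCUUU")
  as_template(sim, sid)
  ph(sim, 51)
  expect_true(strand_info(sim, sid)$folded)

  # empirical unfolding frequency tracks p_rtt
  sim <- new_sim(params_off(p_rtt = 0.3), seed = 16)
  for (i in 1:2000) add_strand(sim, 0, "AAAAGUCUUU")
  ph(sim, 51)
  d <- dump_state(sim)
  unfolded <- sum(!vapply(d$strands, function(s) s$folded, TRUE))
  expect_true(abs(unfolded - 600) < 3 * sqrt(2000 * 0.3 * 0.7))
})

test_that("a class override changes the template rate of that class only", {
  p <- params_off(p_rtt = 0,
                  class_overrides = list(CONTROL = list(p_rtt = 1)))
  sim <- new_sim(p, seed = 17)
  rep_id <- add_strand(sim, 0, "AAAAGUCUUU")
  ctl_id <- add_strand(sim, 0, "AAAUCAGUUU")
  ph(sim, 51)
  expect_true(strand_info(sim, rep_id)$folded)
  expect_false(strand_info(sim, ctl_id)$folded)
})

test_that("Rep binding requires a folded Rep in the compartment", {
  p <- params_off(p_rb = 1, p_rd = 0)
  # no Rep anywhere: the template stays unbound
  sim <- new_sim(p, seed = 18)
  tid <- add_strand(sim, 0, "AAAACUGUUU")
  as_template(sim, tid)
  ph(sim, 52)
  expect_false(strand_info(sim, tid)$rep_bound)

  # a Rep in a different room does not help
  sim <- new_sim(p, seed = 185)
  tid <- add_strand(sim, 0, "AAAACUGUUU")
  add_strand(sim, 5, "AAAAGUCUUU")
  as_template(sim, tid)
  ph(sim, 52)
  expect_false(strand_info(sim, tid)$rep_bound)

  # one Rep, two templates: exactly one gains it (a Rep serves one template)
  sim <- new_sim(p, seed = 19)
  t1 <- add_strand(sim, 0, "AAAACUGUUU")
  t2 <- add_strand(sim, 0, "AAAACUGUUU")
  rep_id <- add_strand(sim, 0, "AAAAGUCUUU")
  as_template(sim, t1)
  as_template(sim, t2)
  ph(sim, 52)
  bound <- c(strand_info(sim, t1)$rep_bound, strand_info(sim, t2)$rep_bound)
  expect_equal(sum(bound), 1)
  expect_true(strand_info(sim, rep_id)$busy_rep)

  # certain drop releases both the template and the Rep
  sim <- new_sim(params_off(p_rd = 1), seed = 20)
  tid <- add_strand(sim, 0, "AAAACUGUUU")
  rep_id <- add_strand(sim, 0, "AAAAGUCUUU")
  ribocell:::sim_bind_rep(sim$xp, tid, rep_id)
  ph(sim, 52)
  expect_false(strand_info(sim, tid)$rep_bound)
  expect_false(strand_info(sim, rep_id)$busy_rep)
})

test_that("Rep occupancy matches the two-state Markov stationary fraction", {
  # bind 0.4 / drop 0.6: stationary bound fraction 0.4
  p <- params_off(p_rb = 0.4, p_rd = 0.6)
  sim <- new_sim(p, seed = 21)
  tid <- add_strand(sim, 0, "AAAACUGUUU")
  add_strand(sim, 0, "AAAAGUCUUU")
  as_template(sim, tid)
  bound <- logical(6000)
  for (i in seq_along(bound)) {
    ph(sim, 52)
    bound[i] <- strand_info(sim, tid)$rep_bound
  }
  frac <- mean(bound[-(1:100)])
  # mean of a two-state chain; allow a generous band for autocorrelation
  expect_true(abs(frac - 0.4) < 0.05)
})

test_that("attraction covers templates with high-fidelity substrates", {
  # certain attraction, perfect fidelity: full complementary coverage
  p <- params_off(p_at = 1, p_fp = 0)
  sim <- new_sim(p, seed = 22)
  set_pool(sim, 0, nt = c(500, 500, 500, 500))
  tid <- add_strand(sim, 0, "AAAAGUCUUU")
  as_template(sim, tid)
  ph(sim, 53)
  info <- strand_info(sim, tid)
  cov <- sum(vapply(info$atts, function(a) length(a$seq), 0L))
  expect_equal(cov, 10)
  for (a in info$atts) {
    expect_true(all(a$ok == 1))
    for (q in seq_along(a$seq)) {
      expect_true(bases_pair(
        ribocell:::int_to_seq(a$seq[q]),
        substr("AAAAGUCUUU", a$start + q, a$start + q)))
    }
  }

  # no attraction at rate zero
  sim <- new_sim(params_off(p_at = 0), seed = 23)
  set_pool(sim, 0, nt = c(10, 10, 10, 10))
  tid <- add_strand(sim, 0, "AAAAGUCUUU")
  as_template(sim, tid)
  ph(sim, 53)
  expect_equal(length(strand_info(sim, tid)$atts), 0)
})

test_that("the mispair fraction among attached nucleotides tracks p_fp", {
  p <- params_off(p_at = 1, p_fp = 0.05)
  sim <- new_sim(p, seed = 24)
  set_pool(sim, 0, nt = c(5000, 5000, 5000, 5000))
  n_t <- 400
  tids <- integer(n_t)
  for (i in seq_len(n_t)) {
    tids[i] <- add_strand(sim, 0, "AAAAGUCUUU")
    as_template(sim, tids[i])
  }
  ph(sim, 53)
  d <- dump_state(sim)
  oks <- unlist(lapply(tids, function(tid) {
    unlist(lapply(d$strands[[tid + 1]]$atts, function(a) a$ok))
  }))
  expect_gt(length(oks), 2000)
  frac <- mean(oks == 0)
  se <- sqrt(0.05 * 0.95 / length(oks))
  expect_true(abs(frac - 0.05) < 4 * se)
})

test_that("template ligation merges adjacent substrates under the flank rule", {
  mk <- function(p, rep_bound = TRUE, ok1 = 1, ok2 = 1, seed = 1) {
    sim <- new_sim(p, seed = seed)
    tid <- add_strand(sim, 0, "AAAAGUCUUU")
    add_attachment(sim, tid, 0, "UU", ok = c(1, ok1))
    add_attachment(sim, tid, 2, "UC", ok = c(ok2, 1))
    if (rep_bound) {
      rep_id <- add_strand(sim, 0, "AAAAGUCUUU")
      ribocell:::sim_bind_rep(sim$xp, tid, rep_id)
    }
    ph(sim, 54)
    length(strand_info(sim, tid)$atts)
  }
  # Rep-catalyzed certain ligation with true flanks merges
  expect_equal(mk(params_off(p_tlr = 1)), 1)
  # a single false flank blocks unless the mispair-ligation draw passes
  expect_equal(mk(params_off(p_tlr = 1, p_flr = 0), ok1 = 0), 2)
  expect_equal(mk(params_off(p_tlr = 1, p_flr = 1), ok1 = 0), 1)
  expect_equal(mk(params_off(p_tlr = 1, p_flr = 0), ok2 = 0), 2)
  # non-enzymatic ligation uses p_tl and ignores flank correctness
  expect_equal(mk(params_off(p_tl = 1), rep_bound = FALSE, ok1 = 0), 1)
  expect_equal(mk(params_off(p_tl = 0), rep_bound = FALSE), 2)

  # Rep-catalyzed ligation over a false flank occurs at about p_flr
  p <- params_off(p_tlr = 1, p_flr = 0.1)
  hits <- 0
  n <- 1500
  sim <- new_sim(p, seed = 30)
  for (i in seq_len(n)) {
    tid <- add_strand(sim, 0, "AAAAGUCUUU")
    add_attachment(sim, tid, 0, "UU", ok = c(1, 0))
    add_attachment(sim, tid, 2, "UC", ok = c(1, 1))
    rep_id <- add_strand(sim, 0, "AAAAGUCUUU")
    ribocell:::sim_bind_rep(sim$xp, tid, rep_id)
  }
  ph(sim, 54)
  d <- dump_state(sim)
  merged <- sum(vapply(Filter(function(s) length(s$atts) > 0 ||
                                (!s$folded), d$strands), function(s) {
    length(s$atts) == 1
  }, TRUE))
  expect_true(abs(merged / n - 0.1) < 4 * sqrt(0.1 * 0.9 / n))
})

test_that("separation releases products as the antiparallel complement", {
  # certain separation releases a ligated product as a folded strand
  sim <- new_sim(params_off(p_sp = 1), seed = 31)
  tid <- add_strand(sim, 0, "AAAAGUCUUU")
  add_attachment(sim, tid, 0, "UUUUCAGAAA")
  ph(sim, 55)
  d <- dump_state(sim)
  expect_equal(length(d$strands[[tid + 1]]$atts), 0)
  prod <- d$strands[[length(d$strands)]]
  expect_true(prod$folded)
  expect_equal(ribocell:::int_to_seq(prod$seq), complement_seq("AAAAGUCUUU"))

  # a released single nucleotide returns to the pool
  sim <- new_sim(params_off(p_sp = 1), seed = 32)
  tid <- add_strand(sim, 0, "AAAAGUCUUU")
  add_attachment(sim, tid, 4, "C")
  ph(sim, 55)
  expect_equal(pool_of(sim, 0)$nt[3], 1)

  # nothing detaches at rate zero
  sim <- new_sim(params_off(p_sp = 0), seed = 33)
  tid <- add_strand(sim, 0, "AAAAGUCUUU")
  add_attachment(sim, tid, 4, "C")
  ph(sim, 55)
  expect_equal(length(strand_info(sim, tid)$atts), 1)
})

test_that("a full replication cycle with perfect fidelity yields complements", {
  # drive one template through attraction/ligation/separation repeatedly;
  # all full-length products must be exact antiparallel complements
  p <- params_off(p_at = 0.01, p_fp = 0, p_tlr = 1, p_sp = 0.8, p_rb = 1)
  sim <- new_sim(p, seed = 34)
  set_pool(sim, 0, nt = c(4000, 4000, 4000, 4000))
  tid <- add_strand(sim, 0, "GCAAGUCUGC")
  rep_id <- add_strand(sim, 0, "AAAAGUCUUU")
  as_template(sim, tid)
  ribocell:::sim_bind_rep(sim$xp, tid, rep_id)
  for (i in 1:400) {
    ph(sim, 53)
    ph(sim, 54)
    ph(sim, 55)
  }
  d <- dump_state(sim)
  prods <- Filter(function(s) s$alive && length(s$seq) == 10, d$strands)
  prods <- Filter(function(s) ribocell:::int_to_seq(s$seq) != "GCAAGUCUGC" &&
                    ribocell:::int_to_seq(s$seq) != "AAAAGUCUUU", prods)
  expect_gt(length(prods), 5)
  for (s in prods) {
    expect_equal(ribocell:::int_to_seq(s$seq), complement_seq("GCAAGUCUGC"))
  }
})
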