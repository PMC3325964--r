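# Amphiphile and protocell events, exercised by running single engine
# phases on hand-built states.  Phase ids: 2 amphiphile turnover,
# 6 membranes (formation/exchange/permeation), 7 break/fuse/divide,
# 8 movement.

cell_params <- function(...) params_off(stage = "true_protocell", ...)

test_that("amphiphile turnover converts, decays and conserves units", {
  sim <- new_sim(cell_params(p_af = 1), seed = 1)
  set_pool(sim, 0, ap = 100)
  ph(sim, 2)
  p <- pool_of(sim, 0)
  expect_equal(p$ap, 0)
  expect_equal(p$am, 100)

  sim <- new_sim(cell_params(p_ad = 1), seed = 2)
  set_pool(sim, 0, am = 70)
  ph(sim, 2)
  p <- pool_of(sim, 0)
  expect_equal(p$ap, 70)
  expect_equal(p$am, 0)
  expect_true(rw_audit(sim)$ok)
})

test_that("Asr catalysis gates on its presence and on the true-protocell stage", {
  # folded Asr present in the true-protocell stage: catalyzed rate applies
  p <- cell_params(p_af = 0, p_afr = 1)
  sim <- new_sim(p, seed = 3)
  set_pool(sim, 0, ap = 40)
  add_strand(sim, 0, "AAAAUCGUUU")
  ph(sim, 2)
  expect_equal(pool_of(sim, 0)$am, 40)

  # the same configuration in the pseudo-protocell stage stays uncatalyzed
  p2 <- params_off(stage = "pseudo_protocell", p_af = 0, p_afr = 1)
  sim <- new_sim(p2, seed = 4)
  set_pool(sim, 0, ap = 40)
  add_strand(sim, 0, "AAAAUCGUUU")
  ph(sim, 2)
  expect_equal(pool_of(sim, 0)$am, 0)
})

test_that("membrane decay releases precursors outside the protocell", {
  sim <- new_sim(cell_params(p_adm = 1), seed = 5)
  ribocell:::sim_make_cell(sim$xp, 4, 50, TRUE)
  ph(sim, 2)
  d <- dump_state(sim)
  expect_equal(d$cells[[1]]$b, 0)
  expect_equal(sum(d$ap), 50)   # all in exterior naked rooms
  expect_true(rw_audit(sim)$ok)
})

test_that("membranes assemble above the lower limit, encompassing the room", {
  p <- cell_params(p_mf = 1, l_am = 100, membrane_form = "constant",
                   outward_permeation = FALSE)
  sim <- new_sim(p, seed = 6)
  set_pool(sim, 0, np = 7, nt = c(1, 2, 3, 4), ap = 5, am = 150)
  sid <- add_strand(sim, 0, "AAAAGUCUUU")
  ph(sim, 6)
  d <- dump_state(sim)
  expect_equal(d$cell[1], 0)
  cl <- d$cells[[1]]
  expect_equal(cl$b, 150)
  expect_equal(cl$np, 7)
  expect_equal(as.integer(cl$nt), c(1, 2, 3, 4))
  expect_equal(cl$ap, 5)
  expect_equal(cl$am, 0)
  expect_true(rw_audit(sim)$ok)

  # below the lower limit no membrane ever forms
  sim <- new_sim(p, seed = 7)
  set_pool(sim, 0, am = 99)
  for (i in 1:50) ph(sim, 6)
  expect_equal(dump_state(sim)$cell[1], -1)
})

test_that("membrane exchange joins free amphiphiles and conserves units", {
  p <- cell_params(p_ajm = 1, l_am = 10)
  sim <- new_sim(p, seed = 8)
  ribocell:::sim_make_cell(sim$xp, 4, 20, TRUE)
  # neighbors of room 4 on a 3x3: rooms 1, 7, 3, 5
  set_pool(sim, 1, am = 5)
  set_pool(sim, 7, am = 6)
  before <- rw_audit(sim)
  ph(sim, 6)
  d <- dump_state(sim)
  expect_equal(d$cells[[1]]$b, 31)
  expect_equal(sum(d$am), 0)
  expect_true(rw_audit(sim)$ok)
  expect_equal(rw_audit(sim)$am_expected, before$am_expected)
})

test_that("interior amphiphiles can join the membrane from inside", {
  p <- cell_params(p_ajm = 1, l_am = 10)
  sim <- new_sim(p, seed = 9)
  set_pool(sim, 4, am = 12)
  ribocell:::sim_make_cell(sim$xp, 4, 20, TRUE)  # encompasses the 12
  ph(sim, 6)
  d <- dump_state(sim)
  expect_equal(d$cells[[1]]$b, 32)
  expect_equal(d$cells[[1]]$am, 0)
})

test_that("the osmotic-pressure effect drives membrane toward RNA-rich cells", {
  # two protocells share an exterior bath; equal membranes, unequal interior
  # RNA: the RNA-rich cell's membrane must grow at the poor one's expense
  p <- cell_params(p_ajm = 0.5, p_alm = 0.5, f_op = 1, l_am = 10)
  sim <- new_sim(p, seed = 10)
  ribocell:::sim_make_cell(sim$xp, 0, 100, TRUE)
  ribocell:::sim_make_cell(sim$xp, 4, 100, TRUE)
  ribocell:::sim_set_pool(sim$xp, 0, 0, c(500L, 500L, 500L, 500L), 0, 0)
  for (i in 1:300) ph(sim, 6)
  d <- dump_state(sim)
  expect_gt(d$cells[[1]]$b, d$cells[[2]]$b + 50)
  expect_true(rw_audit(sim)$ok)
})

test_that("permeation follows the closed forms and spares nucleotides", {
  # at b = l_am the inward rates equal the base probabilities
  p <- cell_params(p_npp = 0.3, p_app = 0.6, f_si = 0, l_am = 100,
                   outward_permeation = FALSE)
  sim <- new_sim(p, seed = 11)
  ribocell:::sim_make_cell(sim$xp, 4, 100, TRUE)
  set_pool(sim, 1, np = 4000, ap = 4000)
  ph(sim, 6)
  d <- dump_state(sim)
  expect_true(abs(d$cells[[1]]$np - 1200) < 3 * sqrt(4000 * 0.3 * 0.7))
  expect_true(abs(d$cells[[1]]$ap - 2400) < 3 * sqrt(4000 * 0.6 * 0.4))

  # even at base probability zero, a swollen membrane admits precursors:
  # inflow = 1 - (l_am/b)^(3/2) = 7/8 at b = 4*l_am
  p <- cell_params(p_npp = 0, p_app = 0, f_si = 0, l_am = 100,
                   outward_permeation = FALSE)
  sim <- new_sim(p, seed = 12)
  ribocell:::sim_make_cell(sim$xp, 4, 400, TRUE)
  set_pool(sim, 1, np = 4000)
  ph(sim, 6)
  d <- dump_state(sim)
  expect_true(abs(d$cells[[1]]$np - 3500) < 3 * sqrt(4000 * 0.875 * 0.125))

  # nucleotides and strands never cross
  p <- cell_params(p_npp = 1, p_app = 1, l_am = 10)
  sim <- new_sim(p, seed = 13)
  ribocell:::sim_make_cell(sim$xp, 4, 40, TRUE)
  set_pool(sim, 1, nt = c(50, 0, 0, 0))
  sid <- add_strand(sim, 1, "AAAAGUCUUU")
  ph(sim, 6)
  d <- dump_state(sim)
  expect_equal(sum(as.integer(d$cells[[1]]$nt)), 0)
  expect_equal(d$nt[2, 1], 50)
  expect_equal(d$strands[[sid + 1]]$room, 1)
})

test_that("division partitions the parent exactly and needs room to divide", {
  # a cell at b = 2*l_am can never divide
  p <- cell_params(p_cd = 1, l_am = 50)
  sim <- new_sim(p, seed = 14)
  ribocell:::sim_make_cell(sim$xp, 4, 100, TRUE)
  for (i in 1:100) ph(sim, 7)
  expect_equal(length(dump_state(sim)$cells), 1)

  # a large cell dividing splits membrane and contents without loss
  sim <- new_sim(p, seed = 15)
  ribocell:::sim_make_cell(sim$xp, 4, 5000, TRUE)
  ribocell:::sim_set_pool(sim$xp, 4, 300, c(40L, 30L, 20L, 10L), 60, 25)
  for (sp in c("REP", "NSR")) {
    for (i in 1:3) add_strand(sim, 4, ribozyme_sequence(sp))
  }
  found <- FALSE
  for (i in 1:50) {
    ph(sim, 7)
    d <- dump_state(sim)
    alive <- Filter(function(cl) cl$alive, d$cells)
    if (length(alive) == 2) { found <- TRUE; break }
  }
  expect_true(found)
  expect_equal(sum(vapply(alive, function(cl) cl$b, 0)), 5000)
  expect_equal(sum(vapply(alive, function(cl) cl$np, 0)), 300)
  expect_equal(sum(vapply(alive, function(cl) cl$am, 0)), 25)
  expect_true(rw_audit(sim)$ok)
})

test_that("division gene loss matches exact enumeration", {
  expect_equal(gene_loss_prob(1), 1)
  expect_equal(gene_loss_prob(2), 0.75)
  expect_equal(gene_loss_prob(3), 1 - (3 / 4)^2)
  for (k in 1:3) {
    expect_equal(gene_loss_enumerate(k), gene_loss_prob(k))
    expect_equal(gene_loss_enumerate(k, n_types = 3),
                 gene_loss_prob(k, n_types = 3))
  }

  # simulated division frequency agrees with the closed form for k = 2
  p <- cell_params(p_cd = 1, l_am = 5)
  losses <- 0
  trials <- 300
  sim <- new_sim(p, seed = 16)
  for (t in seq_len(trials)) {
    sim <- new_sim(p, seed = 1000 + t)
    ribocell:::sim_make_cell(sim$xp, 4, 100000, TRUE)
    for (i in 1:2) add_strand(sim, 4, ribozyme_sequence("REP"))
    for (i in 1:2) add_strand(sim, 4, ribozyme_sequence("NSR"))
    ph(sim, 7)
    d <- dump_state(sim)
    alive_rooms <- vapply(Filter(function(cl) cl$alive, d$cells),
                          function(cl) cl$room, 0)
    if (length(alive_rooms) == 2) {
      has <- sapply(alive_rooms, function(r) {
        cls <- 0L
        for (s in d$strands) if (s$alive && s$room == r) cls <- bitwOr(cls, s$cls)
        bitwAnd(cls, 1L) > 0 && bitwAnd(cls, 2L) > 0
      })
      if (!all(has)) losses <- losses + 1
    } else {
      trials <- trials - 1  # division did not fire this trial
    }
  }
  frac <- losses / trials
  expect_true(abs(frac - 0.75) < 4 * sqrt(0.75 * 0.25 / trials))
})

test_that("fusion merges adjacent protocells into one", {
  p <- cell_params(p_cf = 1, l_am = 5)
  sim <- new_sim(p, seed = 17)
  ribocell:::sim_make_cell(sim$xp, 4, 30, TRUE)
  ribocell:::sim_make_cell(sim$xp, 5, 20, TRUE)
  add_strand(sim, 5, "AAAAGUCUUU")
  ph(sim, 7)
  d <- dump_state(sim)
  alive <- Filter(function(cl) cl$alive, d$cells)
  expect_equal(length(alive), 1)
  expect_equal(alive[[1]]$b, 50)
  # the strand followed the merged interior
  expect_equal(d$strands[[1]]$room, alive[[1]]$room)
  expect_true(rw_audit(sim)$ok)
})

test_that("breakage frees the membrane and contents into a naked room", {
  p <- cell_params(p_cb = 1, l_am = 5)
  sim <- new_sim(p, seed = 18)
  set_pool(sim, 4, np = 9, nt = c(1, 1, 1, 1), ap = 3, am = 2)
  ribocell:::sim_make_cell(sim$xp, 4, 25, TRUE)
  ph(sim, 7)
  d <- dump_state(sim)
  expect_equal(d$cell[5], -1)
  expect_equal(d$np[5], 9)
  expect_equal(d$am[5], 27)  # membrane plus interior free amphiphiles
  expect_equal(d$ap[5], 3)
  expect_true(rw_audit(sim)$ok)
})

test_that("a membrane below two amphiphiles breaks spontaneously", {
  sim <- new_sim(cell_params(l_am = 5), seed = 19)
  ribocell:::sim_make_cell(sim$xp, 4, 1, TRUE)
  ph(sim, 7)
  expect_equal(dump_state(sim)$cell[5], -1)
})

test_that("protocell movement pushes the target room's contents aside", {
  p <- cell_params(p_mc = 1, l_am = 5)
  sim <- new_sim(p, seed = 20)
  ribocell:::sim_make_cell(sim$xp, 4, 30, TRUE)
  for (r in setdiff(0:8, 4)) set_pool(sim, r, np = 10)
  before <- rw_audit(sim)
  ph(sim, 8)
  d <- dump_state(sim)
  expect_equal(d$cell[5], -1)       # moved away from room 4
  expect_equal(sum(d$cell >= 0), 1)
  new_room <- which(d$cell >= 0) - 1
  expect_equal(d$np[new_room + 1], 0)  # its previous contents were pushed out
  a <- rw_audit(sim)
  expect_true(a$ok)
  expect_equal(a$nt_units, before$nt_units)

  # a fully surrounded protocell cannot move
  sim <- new_sim(cell_params(p_mc = 1, l_am = 5, n_grid = 2), seed = 21)
  for (r in 0:3) ribocell:::sim_make_cell(sim$xp, r, 30, TRUE)
  ph(sim, 8)
  d <- dump_state(sim)
  expect_equal(vapply(d$cells, function(cl) cl$room, 0), 0:3)
})
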