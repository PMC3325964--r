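# Independent naive reimplementation of the Monte-Carlo step in plain R.
#
# This oracle follows the engine's documented draw discipline (one uniform
# per choice, binomial counts with the small-mean inversion walk, fixed
# iteration orders) but is written from the algorithm description against
# simple R lists, so a seeded engine run and a seeded oracle run must agree
# state-for-state.  Room and strand indices are 0-based as in the dumps.

o_binv_walk <- function(n, p, u) {
  r <- p / (1 - p)
  pmf <- exp(n * log1p(-p))
  cum <- pmf
  k <- 0
  while (u > cum && k < n) {
    pmf <- pmf * (r * (n - k) / (k + 1))
    k <- k + 1
    cum <- cum + pmf
  }
  k
}

o_bin <- function(n, p) {
  if (n <= 0 || p <= 0) return(0)
  if (p >= 1) return(n)
  pm <- if (p < 0.5) p else 1 - p
  if (n * pm <= 10) {
    u <- runif(1)
    if (p <= 0.5) return(o_binv_walk(n, p, u))
    return(n - o_binv_walk(n, 1 - p, u))
  }
  rbinom(1, n, p)
}

o_pick <- function(k) {  # uniform over 0..k-1
  i <- floor(runif(1) * k)
  if (i >= k) k - 1 else i
}

o_comp <- function(b) bitwXor(b, 1L)
o_pair_wc <- function(x, y) bitwXor(x, 1L) == y
o_pair_wobble <- function(x, y) {
  o_pair_wc(x, y) || (x == 3 && y == 1) || (x == 1 && y == 3)
}

o_classify <- function(seq, D) {
  len <- length(seq)
  if (len < D$dlen || len >= 2 * D$dlen) return(0L)
  mask <- 0L
  for (s0 in 0:(len - D$dlen)) {
    stem <- TRUE
    for (i in 1:D$stem) {
      if (!o_pair_wobble(seq[s0 + D$stem - i + 1], seq[s0 + D$stem + 3 + i + 1])) {
        stem <- FALSE
        break
      }
    }
    if (!stem) next
    for (cl in 1:4) {
      if (identical(seq[(s0 + D$stem + 1):(s0 + D$stem + 4)], D$loops[[cl]])) {
        mask <- bitwOr(mask, bitwShiftL(1L, cl - 1L))
      }
    }
  }
  mask
}

oracle_new <- function(params, spec) {
  P <- unclass(params)
  P$stage_id <- match(P$stage, c("naked", "pseudo_protocell", "true_protocell")) - 1L
  ov <- P$class_overrides
  P$has_ov <- logical(4)
  P$ov_rtt <- rep(P$p_rtt, 4)
  cls_names <- c("REP", "NSR", "ASR", "CONTROL")
  for (nm in names(ov)) {
    ci <- match(nm, cls_names)
    if (!is.null(ov[[nm]]$p_rtt)) {
      P$has_ov[ci] <- TRUE
      P$ov_rtt[ci] <- ov[[nm]]$p_rtt
    }
  }
  D <- list(stem = spec$stem_len, dlen = spec$domain_len,
            loops = lapply(spec$loops, ribocell:::seq_to_int))
  R <- P$n_grid^2
  st <- new.env(parent = emptyenv())
  st$P <- P
  st$D <- D
  st$N <- P$n_grid
  st$R <- R
  st$np <- integer(R)
  st$nt <- matrix(0L, R, 4)
  st$ap <- integer(R)
  st$am <- integer(R)
  st$cellid <- rep(-1L, R)
  st$cells <- list()
  st$strands <- list()
  st
}

oracle_initialize <- function(st) {
  for (j in seq_len(st$P$t_npb)) {
    r <- o_pick(st$R)
    st$np[r + 1] <- st$np[r + 1] + 1L
  }
  for (j in seq_len(st$P$t_apb)) {
    r <- o_pick(st$R)
    st$ap[r + 1] <- st$ap[r + 1] + 1L
  }
  invisible(st)
}

o_new_strand <- function(st, room, seq, folded = TRUE) {
  st$strands[[length(st$strands) + 1]] <- list(
    alive = TRUE, room = room, folded = folded, rep_bound = FALSE,
    bound_rep = -1L, busy = FALSE, bound_tmpl = -1L,
    cls = o_classify(seq, st$D), seq = seq, atts = list())
  length(st$strands) - 1L  # 0-based id
}

# pool accessors: compartment of room r (naked pool or its cell's interior)
o_get <- function(st, r, fld) {
  ci <- st$cellid[r + 1]
  if (ci >= 0) st$cells[[ci + 1]][[fld]]
  else switch(fld, np = st$np[r + 1], nt = st$nt[r + 1, ],
              ap = st$ap[r + 1], am = st$am[r + 1])
}
o_set <- function(st, r, fld, val) {
  ci <- st$cellid[r + 1]
  if (ci >= 0) st$cells[[ci + 1]][[fld]] <- val
  else switch(fld,
              np = st$np[r + 1] <- val, nt = st$nt[r + 1, ] <- val,
              ap = st$ap[r + 1] <- val, am = st$am[r + 1] <- val)
  invisible(NULL)
}

o_neigh <- function(st, r) {  # up, down, left, right (0-based)
  N <- st$N
  row <- r %/% N
  col <- r %% N
  c(((row - 1 + N) %% N) * N + col,
    ((row + 1) %% N) * N + col,
    row * N + (col - 1 + N) %% N,
    row * N + (col + 1) %% N)
}

o_naked_neighbors <- function(st, r) {
  nb <- o_neigh(st, r)
  nb[nb != r & st$cellid[nb + 1] < 0]
}

o_pool_eligible <- function(s) s$alive && s$folded && !s$busy

o_presence <- function(st, bit) {
  out <- logical(st$R)
  for (s in st$strands) {
    if (s$alive && s$folded && !s$busy && bitwAnd(s$cls, bit) > 0) {
      out[s$room + 1] <- TRUE
    }
  }
  out
}

o_bucket <- function(st, only_pool) {
  out <- vector("list", st$R)
  for (i in seq_along(st$strands)) {
    s <- st$strands[[i]]
    if (!s$alive) next
    if (only_pool && !o_pool_eligible(s)) next
    out[[s$room + 1]] <- c(out[[s$room + 1]], i - 1L)
  }
  out
}

o_residues_by_room <- function(st) {
  out <- integer(st$R)
  for (s in st$strands) {
    if (!s$alive) next
    m <- length(s$seq) + sum(vapply(s$atts, function(a) length(a$seq), 0L))
    out[s$room + 1] <- out[s$room + 1] + m
  }
  out
}

# ---- phases ----------------------------------------------------------------

o_phase1 <- function(st) {
  nsr <- o_presence(st, 2L)
  for (r in 0:(st$R - 1)) {
    np <- o_get(st, r, "np")
    nt <- o_get(st, r, "nt")
    if (np > 0) {
      pr <- if (nsr[r + 1]) st$P$p_nfr else st$P$p_nf
      k <- o_bin(np, pr)
      np <- np - k
      for (j in seq_len(k)) {
        b <- o_pick(4)
        nt[b + 1] <- nt[b + 1] + 1
      }
    }
    for (b in 1:4) {
      if (nt[b] > 0) {
        d <- o_bin(nt[b], st$P$p_nd)
        nt[b] <- nt[b] - d
        np <- np + d
      }
    }
    o_set(st, r, "np", np)
    o_set(st, r, "nt", nt)
  }
}

o_phase2 <- function(st) {
  if (st$P$stage_id == 0) return(invisible(NULL))
  asr <- o_presence(st, 4L)
  for (r in 0:(st$R - 1)) {
    ap <- o_get(st, r, "ap")
    am <- o_get(st, r, "am")
    if (ap > 0) {
      pr <- if (st$P$stage_id == 2 && asr[r + 1]) st$P$p_afr else st$P$p_af
      k <- o_bin(ap, pr)
      ap <- ap - k
      am <- am + k
    }
    if (am > 0) {
      d <- o_bin(am, st$P$p_ad)
      am <- am - d
      ap <- ap + d
    }
    o_set(st, r, "ap", ap)
    o_set(st, r, "am", am)
    ci <- st$cellid[r + 1]
    if (ci >= 0 && st$cells[[ci + 1]]$b > 0) {
      nn <- o_naked_neighbors(st, r)
      if (length(nn) > 0) {
        d <- o_bin(st$cells[[ci + 1]]$b, st$P$p_adm)
        st$cells[[ci + 1]]$b <- st$cells[[ci + 1]]$b - d
        for (j in seq_len(d)) {
          q <- nn[o_pick(length(nn)) + 1]
          st$ap[q + 1] <- st$ap[q + 1] + 1L
        }
      }
    }
  }
}

o_phase3 <- function(st) {
  elig <- integer(0)
  for (i in seq_along(st$strands)) {
    s <- st$strands[[i]]
    if (s$alive && !s$busy && !s$rep_bound && length(s$atts) == 0) {
      elig <- c(elig, i - 1L)
    }
  }
  ne <- length(elig)
  if (ne == 0) return(invisible(NULL))
  d_front <- logical(ne)
  d_back <- logical(ne)
  ke <- o_bin(2 * ne, st$P$p_nde)
  placed <- 0
  while (placed < ke) {
    e <- floor(runif(1) * (2 * ne))
    if (e >= 2 * ne) e <- 2 * ne - 1
    ti <- e %/% 2 + 1
    if (e %% 2 == 0) {
      if (!d_front[ti]) { d_front[ti] <- TRUE; placed <- placed + 1 }
    } else {
      if (!d_back[ti]) { d_back[ti] <- TRUE; placed <- placed + 1 }
    }
  }
  split_rates <- st$P$stage_id != 0 && st$P$f_bo != 1
  cum_in <- integer(0); ids_in <- integer(0); tot_in <- 0
  cum_out <- integer(0); ids_out <- integer(0); tot_out <- 0
  for (t in seq_len(ne)) {
    s <- st$strands[[elig[t] + 1]]
    nb <- length(s$seq) - 1 - d_front[t] - d_back[t]
    if (nb <= 0) next
    outside <- st$cellid[s$room + 1] < 0
    if (split_rates && outside) {
      tot_out <- tot_out + nb
      cum_out <- c(cum_out, tot_out)
      ids_out <- c(ids_out, t)
    } else {
      tot_in <- tot_in + nb
      cum_in <- c(cum_in, tot_in)
      ids_in <- c(ids_in, t)
    }
  }
  cuts <- vector("list", ne)
  draw_group <- function(cum, ids, tot, p) {
    kb <- o_bin(tot, p)
    done <- 0
    while (done < kb) {
      g <- floor(runif(1) * tot)
      if (g >= tot) g <- tot - 1
      lo <- which(cum >= g + 1)[1]
      t <- ids[lo]
      before <- if (lo == 1) 0 else cum[lo - 1]
      j <- (g - before) + 1
      if (!(j %in% cuts[[t]])) {
        cuts[[t]] <<- c(cuts[[t]], j)
        done <- done + 1
      }
    }
  }
  draw_group(cum_in, ids_in, tot_in, st$P$p_bb)
  if (split_rates) draw_group(cum_out, ids_out, tot_out, st$P$p_bb * st$P$f_bo)

  for (t in seq_len(ne)) {
    if (!d_front[t] && !d_back[t] && length(cuts[[t]]) == 0) next
    i <- elig[t]
    s <- st$strands[[i + 1]]
    room <- s$room
    np <- o_get(st, room, "np")
    nt <- o_get(st, room, "nt")
    seq <- s$seq
    if (d_back[t]) { seq <- seq[-length(seq)]; np <- np + 1 }
    if (d_front[t]) {
      if (length(seq) > 0) seq <- seq[-1]
      np <- np + 1
    }
    if (length(seq) == 0) {
      st$strands[[i + 1]]$alive <- FALSE
    } else if (length(seq) == 1) {
      nt[seq[1] + 1] <- nt[seq[1] + 1] + 1
      st$strands[[i + 1]]$alive <- FALSE
    } else {
      cv <- sort(cuts[[t]])
      cv <- c(cv, length(seq))
      frags <- list()
      from <- 0
      for (cut in cv) {
        if (cut > length(seq)) cut <- length(seq)
        if (cut <= from) next
        frag <- seq[(from + 1):cut]
        from <- cut
        if (length(frag) == 1) nt[frag[1] + 1] <- nt[frag[1] + 1] + 1
        else frags[[length(frags) + 1]] <- frag
      }
      if (length(frags) == 0) {
        st$strands[[i + 1]]$alive <- FALSE
      } else {
        st$strands[[i + 1]]$seq <- frags[[1]]
        st$strands[[i + 1]]$cls <- o_classify(frags[[1]], st$D)
        for (f in seq_along(frags)[-1]) {
          o_new_strand(st, room, frags[[f]])
        }
      }
    }
    o_set(st, room, "np", np)
    o_set(st, room, "nt", nt)
  }
}

o_phase4 <- function(st) {
  by_room <- o_bucket(st, TRUE)
  for (r in 0:(st$R - 1)) {
    nt <- o_get(st, r, "nt")
    ntot <- sum(nt)
    if (ntot <= 0) next
    k <- o_bin(ntot, st$P$p_rl)
    for (ev in seq_len(k)) {
      nt <- o_get(st, r, "nt")
      ntot <- sum(nt)
      if (ntot <= 0) break
      u <- runif(1) * ntot
      cum <- 0
      base <- 0
      for (b in 0:3) {
        cum <- cum + nt[b + 1]
        if (u < cum) { base <- b; break }
      }
      elig <- integer(0)
      for (sid in by_room[[r + 1]]) {
        if (o_pool_eligible(st$strands[[sid + 1]])) elig <- c(elig, sid)
      }
      m <- (ntot - 1) + 2 * length(elig)
      if (m <= 0) next
      pi <- floor(runif(1) * m)
      if (pi >= m) pi <- m - 1
      if (pi < ntot - 1) {
        w <- nt
        w[base + 1] <- w[base + 1] - 1
        u2 <- runif(1) * (ntot - 1)
        c2 <- 0
        b2 <- 0
        for (b in 0:3) {
          c2 <- c2 + w[b + 1]
          if (u2 < c2) { b2 <- b; break }
        }
        nt[base + 1] <- nt[base + 1] - 1
        nt[b2 + 1] <- nt[b2 + 1] - 1
        o_set(st, r, "nt", nt)
        o_new_strand(st, r, as.integer(c(base, b2)))
      } else {
        si <- (pi - (ntot - 1)) %/% 2
        end <- (pi - (ntot - 1)) %% 2
        sid <- elig[si + 1]
        nt[base + 1] <- nt[base + 1] - 1
        o_set(st, r, "nt", nt)
        seq <- st$strands[[sid + 1]]$seq
        seq <- if (end == 0) c(base, seq) else c(seq, base)
        st$strands[[sid + 1]]$seq <- as.integer(seq)
        st$strands[[sid + 1]]$cls <- o_classify(as.integer(seq), st$D)
      }
    }
  }
}

o_rtt_for <- function(st, s) {
  for (cl in 1:4) {
    if (st$P$has_ov[cl] && bitwAnd(s$cls, bitwShiftL(1L, cl - 1L)) > 0) {
      return(st$P$ov_rtt[cl])
    }
  }
  st$P$p_rtt
}

o_phase51 <- function(st) {
  n0 <- length(st$strands)
  for (i in seq_len(n0)) {
    s <- st$strands[[i]]
    if (!s$alive || s$busy || s$rep_bound || length(s$atts) > 0) next
    prt <- o_rtt_for(st, s)
    if (s$folded) {
      if (runif(1) < prt) st$strands[[i]]$folded <- FALSE
    } else if (st$P$refold) {
      if (runif(1) < 1 - prt) st$strands[[i]]$folded <- TRUE
    }
  }
}

o_phase52 <- function(st) {
  rep_room <- vector("list", st$R)
  for (i in seq_along(st$strands)) {
    s <- st$strands[[i]]
    if (s$alive && s$folded && !s$busy && bitwAnd(s$cls, 1L) > 0) {
      rep_room[[s$room + 1]] <- c(rep_room[[s$room + 1]], i - 1L)
    }
  }
  n0 <- length(st$strands)
  for (i in seq_len(n0)) {
    s <- st$strands[[i]]
    if (!s$alive || s$folded) next
    if (s$rep_bound) {
      if (runif(1) < st$P$p_rd) {
        rid <- s$bound_rep
        st$strands[[rid + 1]]$busy <- FALSE
        st$strands[[rid + 1]]$bound_tmpl <- -1L
        st$strands[[i]]$rep_bound <- FALSE
        st$strands[[i]]$bound_rep <- -1L
      }
    } else {
      if (length(rep_room[[s$room + 1]]) == 0) next
      reps <- integer(0)
      for (sid in rep_room[[s$room + 1]]) {
        if (!st$strands[[sid + 1]]$busy) reps <- c(reps, sid)
      }
      if (length(reps) == 0) next
      if (runif(1) < st$P$p_rb) {
        rid <- reps[o_pick(length(reps)) + 1]
        st$strands[[i]]$rep_bound <- TRUE
        st$strands[[i]]$bound_rep <- rid
        st$strands[[rid + 1]]$busy <- TRUE
        st$strands[[rid + 1]]$bound_tmpl <- i - 1L
      }
    }
  }
}

o_insert_att <- function(atts, a) {
  pos <- 1
  while (pos <= length(atts) && atts[[pos]]$start < a$start) pos <- pos + 1
  append(atts, list(a), after = pos - 1)
}

# one site-filling attempt at 0-based position pos; returns next position
o_attract_at <- function(st, i, by_room, pos, stretch_end) {
  s <- st$strands[[i]]
  room <- s$room
  nt <- o_get(st, room, "nt")
  ntot <- sum(nt)
  oligs <- integer(0)
  for (sid in by_room[[room + 1]]) {
    o <- st$strands[[sid + 1]]
    if (o_pool_eligible(o) && pos + length(o$seq) - 1 <= stretch_end) {
      oligs <- c(oligs, sid)
    }
  }
  cc <- ntot + length(oligs)
  if (cc <= 0) return(pos + 1)
  ci <- floor(runif(1) * cc)
  if (ci >= cc) ci <- cc - 1
  if (ci < ntot) {
    tb <- s$seq[pos + 1]
    if (runif(1) < 1 - st$P$p_fp) {
      base <- o_comp(tb)
      okf <- 1L
    } else {
      alt <- o_pick(3)
      seen <- 0
      base <- 0L
      for (b in 0:3) {
        if (b == o_comp(tb)) next
        if (seen == alt) { base <- b; break }
        seen <- seen + 1
      }
      okf <- 0L
    }
    if (nt[base + 1] <= 0) return(pos + 1)
    nt[base + 1] <- nt[base + 1] - 1
    o_set(st, room, "nt", nt)
    a <- list(start = pos, ligated = FALSE, seq = as.integer(base), ok = okf,
              paired = 1L)
    st$strands[[i]]$atts <- o_insert_att(st$strands[[i]]$atts, a)
    return(pos + 1)
  }
  oid <- oligs[ci - ntot + 1]
  o <- st$strands[[oid + 1]]
  L <- length(o$seq)
  al <- rev(o$seq)
  ok <- integer(L)
  for (j in seq_len(L)) {
    if (o_pair_wc(al[j], s$seq[pos + j])) {
      ok[j] <- 1L
    } else if (runif(1) < st$P$p_fp) {
      ok[j] <- 0L
    } else {
      return(pos + 1)
    }
  }
  st$strands[[oid + 1]]$alive <- FALSE
  a <- list(start = pos, ligated = FALSE, seq = al, ok = ok,
            paired = rep(1L, L))
  st$strands[[i]]$atts <- o_insert_att(st$strands[[i]]$atts, a)
  pos + L
}

# growth sites of a room's templates: per uncovered stretch, the site next
# to a flanking attachment (left preferred) or a bare-template nucleation
o_growth_sites <- function(st, tmpls) {
  out <- list()
  for (ti in tmpls) {
    s <- st$strands[[ti + 1]]
    if (!s$alive || s$folded) next
    len <- length(s$seq)
    cur <- 0
    n_att <- length(s$atts)
    for (ai in seq_len(n_att + 1)) {
      upto <- if (ai <= n_att) s$atts[[ai]]$start else len
      if (upto > cur) {
        a0 <- cur
        b0 <- upto - 1
        left_flank <- cur > 0
        right_flank <- upto < len
        g <- if (left_flank) {
          list(tmpl = ti, pos = a0, a0 = a0, b0 = b0,
               align_end = FALSE, bare = FALSE)
        } else if (right_flank) {
          list(tmpl = ti, pos = b0, a0 = a0, b0 = b0,
               align_end = TRUE, bare = FALSE)
        } else {
          list(tmpl = ti, pos = -1, a0 = a0, b0 = b0,
               align_end = FALSE, bare = TRUE)
        }
        out[[length(out) + 1]] <- g
      }
      if (ai <= n_att) cur <- s$atts[[ai]]$start + length(s$atts[[ai]]$seq)
    }
  }
  out
}

# one site-filling attempt with explicit stretch and alignment (i is a
# 0-based strand id, matching the engine's growth-site records)
o_attract_site <- function(st, i, by_room, pos, a0, b0, align_end) {
  i <- i + 1
  s <- st$strands[[i]]
  room <- s$room
  nt <- o_get(st, room, "nt")
  ntot <- sum(nt)
  oligs <- integer(0)
  for (sid in by_room[[room + 1]]) {
    o <- st$strands[[sid + 1]]
    if (!o_pool_eligible(o)) next
    L <- length(o$seq)
    fits <- if (align_end) pos - L + 1 >= a0 else pos + L - 1 <= b0
    if (fits) oligs <- c(oligs, sid)
  }
  cc <- ntot + length(oligs)
  if (cc <= 0) return(invisible(NULL))
  ci <- floor(runif(1) * cc)
  if (ci >= cc) ci <- cc - 1
  if (ci < ntot) {
    tb <- s$seq[pos + 1]
    if (runif(1) < 1 - st$P$p_fp) {
      base <- o_comp(tb)
      okf <- 1L
    } else {
      alt <- o_pick(3)
      seen <- 0
      base <- 0L
      for (b in 0:3) {
        if (b == o_comp(tb)) next
        if (seen == alt) { base <- b; break }
        seen <- seen + 1
      }
      okf <- 0L
    }
    if (nt[base + 1] <= 0) return(invisible(NULL))
    nt[base + 1] <- nt[base + 1] - 1
    o_set(st, room, "nt", nt)
    a <- list(start = pos, ligated = FALSE, seq = as.integer(base), ok = okf,
              paired = 1L)
    st$strands[[i]]$atts <- o_insert_att(st$strands[[i]]$atts, a)
    return(invisible(NULL))
  }
  oid <- oligs[ci - ntot + 1]
  o <- st$strands[[oid + 1]]
  L <- length(o$seq)
  start <- if (align_end) pos - L + 1 else pos
  al <- rev(o$seq)
  ok <- integer(L)
  for (j in seq_len(L)) {
    if (o_pair_wc(al[j], s$seq[start + j])) {
      ok[j] <- 1L
    } else if (runif(1) < st$P$p_fp) {
      ok[j] <- 0L
    } else {
      return(invisible(NULL))
    }
  }
  st$strands[[oid + 1]]$alive <- FALSE
  a <- list(start = start, ligated = FALSE, seq = al, ok = ok,
            paired = rep(1L, L))
  st$strands[[i]]$atts <- o_insert_att(st$strands[[i]]$atts, a)
  invisible(NULL)
}

o_phase53_flux <- function(st, by_room) {
  for (r in 0:(st$R - 1)) {
    tmpls <- by_room[[r + 1]]
    if (length(tmpls) == 0) next
    sites <- o_growth_sites(st, tmpls)
    if (length(sites) == 0) next
    nt <- o_get(st, r, "nt")
    S0 <- sum(nt)
    for (sid in tmpls) {
      if (o_pool_eligible(st$strands[[sid + 1]])) S0 <- S0 + 1
    }
    if (S0 <= 0) next
    k <- o_bin(S0, st$P$p_at)
    for (ev in seq_len(k)) {
      if (length(sites) == 0) break
      g <- sites[[o_pick(length(sites)) + 1]]
      pos <- g$pos
      if (g$bare) pos <- g$a0 + o_pick(g$b0 - g$a0 + 1)
      o_attract_site(st, g$tmpl, by_room, pos, g$a0, g$b0, g$align_end)
      # refresh only the touched template's entries (drop, then append)
      keep <- vapply(sites, function(x) x$tmpl != g$tmpl, TRUE)
      sites <- c(sites[keep], o_growth_sites(st, g$tmpl))
    }
  }
}

o_phase53 <- function(st) {
  by_room <- o_bucket(st, FALSE)
  if (st$P$attraction == "flux") {
    o_phase53_flux(st, by_room)
    return(invisible(NULL))
  }
  n0 <- length(st$strands)
  for (i in seq_len(n0)) {
    if (!st$strands[[i]]$alive || st$strands[[i]]$folded) next
    len <- length(st$strands[[i]]$seq)
    cov <- sum(vapply(st$strands[[i]]$atts, function(a) length(a$seq), 0L))
    room <- st$strands[[i]]$room
    if (st$P$attraction == "template") {
      if (cov >= len) next
      if (runif(1) >= st$P$p_at) next
      stretches <- list()
      cur <- 0
      for (a in st$strands[[i]]$atts) {
        if (a$start > cur) stretches[[length(stretches) + 1]] <- c(cur, a$start - 1)
        cur <- a$start + length(a$seq)
      }
      if (cur < len) stretches[[length(stretches) + 1]] <- c(cur, len - 1)
      for (g in stretches) {
        pos <- g[1]
        while (pos <= g[2]) {
          pos <- o_attract_at(st, i, by_room, pos, g[2])
        }
      }
      next
    }
    k <- o_bin(len - cov, st$P$p_at)
    for (ev in seq_len(k)) {
      s <- st$strands[[i]]
      unc <- integer(0)
      cur <- 0
      for (a in s$atts) {
        if (a$start > cur) unc <- c(unc, cur:(a$start - 1))
        cur <- a$start + length(a$seq)
      }
      if (cur < len) unc <- c(unc, cur:(len - 1))
      if (length(unc) == 0) break
      pidx <- o_pick(length(unc)) + 1
      pos <- unc[pidx]
      ia <- pidx
      ib <- pidx
      while (ia > 1 && unc[ia - 1] == unc[ia] - 1) ia <- ia - 1
      while (ib < length(unc) && unc[ib + 1] == unc[ib] + 1) ib <- ib + 1
      a0 <- unc[ia]
      b0 <- unc[ib]
      glen <- b0 - a0 + 1
      nt <- o_get(st, room, "nt")
      ntot <- sum(nt)
      oligs <- integer(0)
      for (sid in by_room[[room + 1]]) {
        o <- st$strands[[sid + 1]]
        if (o_pool_eligible(o) && length(o$seq) <= glen) oligs <- c(oligs, sid)
      }
      cc <- ntot + length(oligs)
      if (cc <= 0) next
      ci <- floor(runif(1) * cc)
      if (ci >= cc) ci <- cc - 1
      if (ci < ntot) {
        tb <- s$seq[pos + 1]
        if (runif(1) < 1 - st$P$p_fp) {
          base <- o_comp(tb)
          okf <- 1L
        } else {
          alt <- o_pick(3)
          seen <- 0
          base <- 0L
          for (b in 0:3) {
            if (b == o_comp(tb)) next
            if (seen == alt) { base <- b; break }
            seen <- seen + 1
          }
          okf <- 0L
        }
        if (nt[base + 1] <= 0) next
        nt[base + 1] <- nt[base + 1] - 1
        o_set(st, room, "nt", nt)
        a <- list(start = pos, ligated = FALSE, seq = as.integer(base),
                  ok = okf, paired = 1L)
        st$strands[[i]]$atts <- o_insert_att(st$strands[[i]]$atts, a)
      } else {
        oid <- oligs[ci - ntot + 1]
        o <- st$strands[[oid + 1]]
        L <- length(o$seq)
        lo <- max(a0, pos - L + 1)
        hi <- min(pos, b0 - L + 1)
        start <- lo + o_pick(hi - lo + 1)
        al <- rev(o$seq)
        ok <- integer(L)
        fail <- FALSE
        for (j in seq_len(L)) {
          if (o_pair_wc(al[j], s$seq[start + j])) {
            ok[j] <- 1L
          } else if (runif(1) < st$P$p_fp) {
            ok[j] <- 0L
          } else {
            fail <- TRUE
            break
          }
        }
        if (fail) next
        st$strands[[oid + 1]]$alive <- FALSE
        a <- list(start = start, ligated = FALSE, seq = al, ok = ok,
                  paired = rep(1L, L))
        st$strands[[i]]$atts <- o_insert_att(st$strands[[i]]$atts, a)
      }
    }
  }
}

o_phase54 <- function(st) {
  n0 <- length(st$strands)
  for (i in seq_len(n0)) {
    s <- st$strands[[i]]
    if (!s$alive || s$folded || length(s$atts) < 2) next
    atts <- s$atts
    j <- 1
    while (j + 1 <= length(atts)) {
      a <- atts[[j]]
      b <- atts[[j + 1]]
      if (a$start + length(a$seq) != b$start) { j <- j + 1; next }
      pr <- if (s$rep_bound) st$P$p_tlr else st$P$p_tl
      go <- runif(1) < pr
      if (go && s$rep_bound &&
          (a$ok[length(a$ok)] == 0 || b$ok[1] == 0)) {
        go <- runif(1) < st$P$p_flr
      }
      if (go) {
        a$seq <- c(a$seq, b$seq)
        a$ok <- c(a$ok, b$ok)
        a$paired <- c(a$paired, b$paired)
        if (s$rep_bound) a$ligated <- TRUE
        atts[[j]] <- a
        atts[[j + 1]] <- NULL
      } else {
        j <- j + 1
      }
    }
    st$strands[[i]]$atts <- atts
  }
}

o_phase55 <- function(st) {
  n0 <- length(st$strands)
  for (i in seq_len(n0)) {
    if (!st$strands[[i]]$alive || st$strands[[i]]$folded ||
        length(st$strands[[i]]$atts) == 0) next
    room <- st$strands[[i]]$room
    j <- 1
    while (j <= length(st$strands[[i]]$atts)) {
      a <- st$strands[[i]]$atts[[j]]
      if (st$P$separation == "ratchet") {
        for (q in seq_along(a$paired)) {
          if (a$paired[q] == 1 && runif(1) < st$P$p_sp) a$paired[q] <- 0L
        }
        st$strands[[i]]$atts[[j]] <- a
        rel <- all(a$paired == 0)
      } else if (st$P$separation == "processive" && isTRUE(a$ligated) &&
                 length(a$seq) < length(st$strands[[i]]$seq)) {
        rel <- FALSE  # bound intermediate: no draw
      } else {
        p_rel <- st$P$p_sp^length(a$seq)
        rel <- if (p_rel >= 1) TRUE else if (p_rel <= 0) FALSE else runif(1) < p_rel
      }
      if (rel) {
        st$strands[[i]]$atts[[j]] <- NULL
        if (length(a$seq) == 1) {
          nt <- o_get(st, room, "nt")
          nt[a$seq[1] + 1] <- nt[a$seq[1] + 1] + 1
          o_set(st, room, "nt", nt)
        } else {
          o_new_strand(st, room, rev(a$seq))
        }
      } else {
        j <- j + 1
      }
    }
  }
}

o_memb_form_p <- function(st, a) {
  if (a < st$P$l_am) return(0)
  if (st$P$membrane_form == "constant") return(st$P$p_mf)
  st$P$p_mf * (1 - st$P$l_am / (a + 1))
}

o_phase6 <- function(st) {
  if (st$P$stage_id == 0) return(invisible(NULL))
  # 6a formation
  for (r in 0:(st$R - 1)) {
    if (st$cellid[r + 1] >= 0) next
    pf <- o_memb_form_p(st, st$am[r + 1])
    if (pf <= 0) next
    if (runif(1) < pf) {
      st$cells[[length(st$cells) + 1]] <- list(
        alive = TRUE, room = r, b = st$am[r + 1], np = st$np[r + 1],
        nt = st$nt[r + 1, ], ap = st$ap[r + 1], am = 0L)
      st$np[r + 1] <- 0L
      st$nt[r + 1, ] <- 0L
      st$ap[r + 1] <- 0L
      st$am[r + 1] <- 0L
      st$cellid[r + 1] <- length(st$cells) - 1L
    }
  }
  res_room <- o_residues_by_room(st)
  # 6b exchange
  for (r in 0:(st$R - 1)) {
    ci <- st$cellid[r + 1]
    if (ci < 0) next
    nbr <- o_neigh(st, r)
    for (q in nbr) {
      if (q == r || st$cellid[q + 1] >= 0) next
      if (st$am[q + 1] > 0) {
        k <- o_bin(st$am[q + 1], st$P$p_ajm)
        st$am[q + 1] <- st$am[q + 1] - k
        st$cells[[ci + 1]]$b <- st$cells[[ci + 1]]$b + k
      }
    }
    if (st$cells[[ci + 1]]$am > 0) {
      k <- o_bin(st$cells[[ci + 1]]$am, st$P$p_ajm)
      st$cells[[ci + 1]]$am <- st$cells[[ci + 1]]$am - k
      st$cells[[ci + 1]]$b <- st$cells[[ci + 1]]$b + k
    }
    if (st$cells[[ci + 1]]$b >= 2) {
      nn <- o_naked_neighbors(st, r)
      if (length(nn) > 0) {
        n <- sum(st$cells[[ci + 1]]$nt) + res_room[r + 1]
        b <- st$cells[[ci + 1]]$b
        pl <- st$P$p_alm / (1 + st$P$f_op * n / (b / 2)^1.5)
        k <- o_bin(b, pl)
        st$cells[[ci + 1]]$b <- b - k
        for (j in seq_len(k)) {
          q <- nn[o_pick(length(nn)) + 1]
          st$am[q + 1] <- st$am[q + 1] + 1L
        }
      }
    }
  }
  # 6c permeation
  for (r in 0:(st$R - 1)) {
    ci <- st$cellid[r + 1]
    if (ci < 0) next
    b <- st$cells[[ci + 1]]$b
    if (b < st$P$l_am) next
    n <- sum(st$cells[[ci + 1]]$nt) + res_room[r + 1]
    shrink <- (st$P$l_am / b)^1.5
    pin_np <- (1 - (1 - st$P$p_npp) * shrink) / (1 + st$P$f_si * n / (b / 2)^1.5)
    pin_ap <- 1 - (1 - st$P$p_app) * shrink
    if (pin_np < 0) pin_np <- 0
    if (pin_ap < 0) pin_ap <- 0
    nbr <- o_neigh(st, r)
    for (q in nbr) {
      if (q == r || st$cellid[q + 1] >= 0) next
      if (st$np[q + 1] > 0) {
        k <- o_bin(st$np[q + 1], pin_np)
        st$np[q + 1] <- st$np[q + 1] - k
        st$cells[[ci + 1]]$np <- st$cells[[ci + 1]]$np + k
      }
      if (st$ap[q + 1] > 0) {
        k <- o_bin(st$ap[q + 1], pin_ap)
        st$ap[q + 1] <- st$ap[q + 1] - k
        st$cells[[ci + 1]]$ap <- st$cells[[ci + 1]]$ap + k
      }
    }
    if (st$P$outward_permeation) {
      nn <- o_naked_neighbors(st, r)
      if (length(nn) > 0) {
        if (st$cells[[ci + 1]]$np > 0) {
          k <- o_bin(st$cells[[ci + 1]]$np, pin_np)
          st$cells[[ci + 1]]$np <- st$cells[[ci + 1]]$np - k
          for (j in seq_len(k)) {
            q <- nn[o_pick(length(nn)) + 1]
            st$np[q + 1] <- st$np[q + 1] + 1L
          }
        }
        if (st$cells[[ci + 1]]$ap > 0) {
          k <- o_bin(st$cells[[ci + 1]]$ap, pin_ap)
          st$cells[[ci + 1]]$ap <- st$cells[[ci + 1]]$ap - k
          for (j in seq_len(k)) {
            q <- nn[o_pick(length(nn)) + 1]
            st$ap[q + 1] <- st$ap[q + 1] + 1L
          }
        }
      }
    }
  }
}

o_do_break <- function(st, ci) {
  cl <- st$cells[[ci + 1]]
  r <- cl$room
  st$np[r + 1] <- st$np[r + 1] + cl$np
  st$nt[r + 1, ] <- st$nt[r + 1, ] + cl$nt
  st$ap[r + 1] <- st$ap[r + 1] + cl$ap
  st$am[r + 1] <- st$am[r + 1] + cl$am + cl$b
  st$cellid[r + 1] <- -1L
  st$cells[[ci + 1]]$alive <- FALSE
}

o_phase7 <- function(st) {
  if (st$P$stage_id == 0) return(invisible(NULL))
  # break: cells in room order
  order <- integer(0)
  for (r in 0:(st$R - 1)) if (st$cellid[r + 1] >= 0) order <- c(order, st$cellid[r + 1])
  for (ci in order) {
    if (!st$cells[[ci + 1]]$alive) next
    if (st$cells[[ci + 1]]$b < 2) { o_do_break(st, ci); next }
    if (runif(1) < st$P$p_cb) o_do_break(st, ci)
  }
  # fusion via down/right neighbors
  for (r in 0:(st$R - 1)) {
    if (st$cellid[r + 1] < 0) next
    nbr <- o_neigh(st, r)
    for (q in c(nbr[2], nbr[4])) {
      if (q == r || st$cellid[r + 1] < 0 || st$cellid[q + 1] < 0) next
      if (runif(1) >= st$P$p_cf) next
      ca <- st$cellid[r + 1]
      cb <- st$cellid[q + 1]
      keep_a <- runif(1) < 0.5
      keep <- if (keep_a) ca else cb
      gone <- if (keep_a) cb else ca
      room_gone <- st$cells[[gone + 1]]$room
      G <- st$cells[[gone + 1]]
      st$cells[[keep + 1]]$b <- st$cells[[keep + 1]]$b + G$b
      st$cells[[keep + 1]]$np <- st$cells[[keep + 1]]$np + G$np
      st$cells[[keep + 1]]$nt <- st$cells[[keep + 1]]$nt + G$nt
      st$cells[[keep + 1]]$ap <- st$cells[[keep + 1]]$ap + G$ap
      st$cells[[keep + 1]]$am <- st$cells[[keep + 1]]$am + G$am
      kroom <- st$cells[[keep + 1]]$room
      for (i in seq_along(st$strands)) {
        if (st$strands[[i]]$alive && st$strands[[i]]$room == room_gone) {
          st$strands[[i]]$room <- kroom
        }
      }
      st$cellid[room_gone + 1] <- -1L
      st$cells[[gone + 1]]$alive <- FALSE
    }
  }
  # division
  order <- integer(0)
  for (r in 0:(st$R - 1)) {
    ci <- st$cellid[r + 1]
    if (ci >= 0 && st$cells[[ci + 1]]$alive) order <- c(order, ci)
  }
  for (ci in order) {
    cl <- st$cells[[ci + 1]]
    if (!cl$alive || cl$b < 2) next
    pd <- st$P$p_cd * (1 - 2 * st$P$l_am / cl$b)
    if (pd <= 0) next
    if (runif(1) >= pd) next
    nn <- o_naked_neighbors(st, cl$room)
    if (length(nn) == 0) next
    target <- nn[o_pick(length(nn)) + 1]
    b_stay <- o_bin(cl$b, 0.5)
    np_stay <- o_bin(cl$np, 0.5)
    nt_stay <- integer(4)
    for (b in 1:4) nt_stay[b] <- o_bin(cl$nt[b], 0.5)
    ap_stay <- o_bin(cl$ap, 0.5)
    am_stay <- o_bin(cl$am, 0.5)
    movers <- integer(0)
    for (i in seq_along(st$strands)) {
      s <- st$strands[[i]]
      if (!s$alive || s$room != cl$room) next
      if (s$busy) next
      stays <- runif(1) < 0.5
      if (!stays) {
        movers <- c(movers, i - 1L)
        if (s$rep_bound) movers <- c(movers, s$bound_rep)
      }
    }
    push_to <- o_naked_neighbors(st, target)
    push_to <- push_to[push_to != target]
    nc <- list(alive = TRUE, room = target, b = cl$b - b_stay,
               np = cl$np - np_stay, nt = cl$nt - nt_stay,
               ap = cl$ap - ap_stay, am = cl$am - am_stay)
    st$cells[[ci + 1]]$b <- b_stay
    st$cells[[ci + 1]]$np <- np_stay
    st$cells[[ci + 1]]$nt <- nt_stay
    st$cells[[ci + 1]]$ap <- ap_stay
    st$cells[[ci + 1]]$am <- am_stay
    if (length(push_to) > 0) {
      for (j in seq_len(st$np[target + 1])) {
        q <- push_to[o_pick(length(push_to)) + 1]
        st$np[q + 1] <- st$np[q + 1] + 1L
      }
      for (b in 1:4) {
        for (j in seq_len(st$nt[target + 1, b])) {
          q <- push_to[o_pick(length(push_to)) + 1]
          st$nt[q + 1, b] <- st$nt[q + 1, b] + 1L
        }
      }
      for (j in seq_len(st$ap[target + 1])) {
        q <- push_to[o_pick(length(push_to)) + 1]
        st$ap[q + 1] <- st$ap[q + 1] + 1L
      }
      for (j in seq_len(st$am[target + 1])) {
        q <- push_to[o_pick(length(push_to)) + 1]
        st$am[q + 1] <- st$am[q + 1] + 1L
      }
      st$np[target + 1] <- 0L
      st$nt[target + 1, ] <- 0L
      st$ap[target + 1] <- 0L
      st$am[target + 1] <- 0L
      for (i in seq_along(st$strands)) {
        if (st$strands[[i]]$alive && st$strands[[i]]$room == target) {
          st$strands[[i]]$room <- push_to[o_pick(length(push_to)) + 1]
        }
      }
    } else {
      nc$np <- nc$np + st$np[target + 1]
      nc$nt <- nc$nt + st$nt[target + 1, ]
      nc$ap <- nc$ap + st$ap[target + 1]
      nc$am <- nc$am + st$am[target + 1]
      st$np[target + 1] <- 0L
      st$nt[target + 1, ] <- 0L
      st$ap[target + 1] <- 0L
      st$am[target + 1] <- 0L
    }
    st$cells[[length(st$cells) + 1]] <- nc
    st$cellid[target + 1] <- length(st$cells) - 1L
    for (id in movers) st$strands[[id + 1]]$room <- target
  }
}

o_move_counts <- function(st, fld, delta, r, nn, snap, p) {
  if (snap <= 0) return(delta)
  k <- o_bin(snap, p)
  if (k <= 0) return(delta)
  if (fld == "np") st$np[r + 1] <- st$np[r + 1] - k
  else if (fld == "ap") st$ap[r + 1] <- st$ap[r + 1] - k
  else if (fld == "am") st$am[r + 1] <- st$am[r + 1] - k
  else st$nt[r + 1, as.integer(substring(fld, 3))] <-
      st$nt[r + 1, as.integer(substring(fld, 3))] - k
  rem <- k
  t <- length(nn)
  if (t > 1) {
    for (i in seq_len(t - 1)) {
      if (rem <= 0) break
      ki <- o_bin(rem, 1 / (t - i + 1))
      delta[nn[i] + 1] <- delta[nn[i] + 1] + ki
      rem <- rem - ki
    }
  }
  delta[nn[t] + 1] <- delta[nn[t] + 1] + rem
  delta
}

o_phase8 <- function(st) {
  naked_stage <- st$P$stage_id == 0
  rna_moves <- naked_stage || st$P$outside_rna_moves
  snp <- st$np
  snt <- st$nt
  sap <- st$ap
  sam <- st$am
  dnp <- integer(st$R)
  dnt <- matrix(0L, st$R, 4)
  dap <- integer(st$R)
  dam <- integer(st$R)
  for (r in 0:(st$R - 1)) {
    if (st$cellid[r + 1] >= 0) next
    nn <- o_naked_neighbors(st, r)
    if (length(nn) == 0) next
    dnp <- o_move_counts(st, "np", dnp, r, nn, snp[r + 1], st$P$p_mv)
    if (rna_moves) {
      for (b in 1:4) {
        tmp <- o_move_counts(st, paste0("nt", b), dnt[, b], r, nn,
                             snt[r + 1, b], st$P$p_mv)
        dnt[, b] <- tmp
      }
    }
    if (!naked_stage) {
      dap <- o_move_counts(st, "ap", dap, r, nn, sap[r + 1], st$P$p_mv)
      dam <- o_move_counts(st, "am", dam, r, nn, sam[r + 1], st$P$p_mv)
    }
  }
  st$np <- st$np + dnp
  st$nt <- st$nt + dnt
  st$ap <- st$ap + dap
  st$am <- st$am + dam
  if (rna_moves) {
    n0 <- length(st$strands)
    for (i in seq_len(n0)) {
      s <- st$strands[[i]]
      if (!s$alive || s$busy || s$rep_bound) next
      if (st$cellid[s$room + 1] >= 0) next
      m <- length(s$seq) + sum(vapply(s$atts, function(a) length(a$seq), 0L))
      pm <- st$P$p_mv / m^(1 / 3)
      nn <- o_naked_neighbors(st, s$room)
      if (length(nn) == 0) next
      if (runif(1) < pm) {
        st$strands[[i]]$room <- nn[o_pick(length(nn)) + 1]
      }
    }
  }
  if (!naked_stage) {
    order <- integer(0)
    for (r in 0:(st$R - 1)) {
      ci <- st$cellid[r + 1]
      if (ci >= 0 && st$cells[[ci + 1]]$alive) order <- c(order, ci)
    }
    for (ci in order) {
      if (!st$cells[[ci + 1]]$alive) next
      if (runif(1) >= st$P$p_mc) next
      origin <- st$cells[[ci + 1]]$room
      nn <- o_naked_neighbors(st, origin)
      if (length(nn) == 0) next
      target <- nn[o_pick(length(nn)) + 1]
      interior <- integer(0)
      for (i in seq_along(st$strands)) {
        if (st$strands[[i]]$alive && st$strands[[i]]$room == origin) {
          interior <- c(interior, i)
        }
      }
      st$cellid[origin + 1] <- -1L
      push_to <- o_naked_neighbors(st, target)
      push_to <- push_to[push_to != target]
      for (j in seq_len(st$np[target + 1])) {
        q <- push_to[o_pick(length(push_to)) + 1]
        st$np[q + 1] <- st$np[q + 1] + 1L
      }
      for (b in 1:4) {
        for (j in seq_len(st$nt[target + 1, b])) {
          q <- push_to[o_pick(length(push_to)) + 1]
          st$nt[q + 1, b] <- st$nt[q + 1, b] + 1L
        }
      }
      for (j in seq_len(st$ap[target + 1])) {
        q <- push_to[o_pick(length(push_to)) + 1]
        st$ap[q + 1] <- st$ap[q + 1] + 1L
      }
      for (j in seq_len(st$am[target + 1])) {
        q <- push_to[o_pick(length(push_to)) + 1]
        st$am[q + 1] <- st$am[q + 1] + 1L
      }
      st$np[target + 1] <- 0L
      st$nt[target + 1, ] <- 0L
      st$ap[target + 1] <- 0L
      st$am[target + 1] <- 0L
      for (i in seq_along(st$strands)) {
        if (st$strands[[i]]$alive && st$strands[[i]]$room == target) {
          st$strands[[i]]$room <- push_to[o_pick(length(push_to)) + 1]
        }
      }
      st$cellid[target + 1] <- ci
      st$cells[[ci + 1]]$room <- target
      for (i in interior) st$strands[[i]]$room <- target
    }
  }
}

o_compact <- function(st) {
  dead <- sum(!vapply(st$strands, function(s) s$alive, TRUE))
  n <- length(st$strands)
  if (dead * 2 < n || dead < 64) return(invisible(NULL))
  remap <- rep(-1L, n)
  keep <- list()
  for (i in seq_len(n)) {
    if (st$strands[[i]]$alive) {
      keep[[length(keep) + 1]] <- st$strands[[i]]
      remap[i] <- length(keep) - 1L
    }
  }
  for (i in seq_along(keep)) {
    if (keep[[i]]$bound_rep >= 0) keep[[i]]$bound_rep <- remap[keep[[i]]$bound_rep + 1]
    if (keep[[i]]$bound_tmpl >= 0) keep[[i]]$bound_tmpl <- remap[keep[[i]]$bound_tmpl + 1]
  }
  st$strands <- keep
}

oracle_step <- function(st) {
  o_phase1(st)
  o_phase2(st)
  o_phase3(st)
  o_phase4(st)
  o_phase51(st)
  o_phase52(st)
  o_phase53(st)
  o_phase54(st)
  o_phase55(st)
  o_phase6(st)
  o_phase7(st)
  o_phase8(st)
  o_compact(st)
  invisible(st)
}

# normalize an engine dump and an oracle state to a comparable form
normalize_engine <- function(d) {
  m <- unname(d$nt)
  storage.mode(m) <- "integer"
  list(
    np = as.integer(d$np), nt = m, ap = as.integer(d$ap),
    am = as.integer(d$am), cell = as.integer(d$cell),
    cells = lapply(d$cells, function(cl) {
      list(alive = cl$alive, room = as.integer(cl$room), b = as.integer(cl$b),
           np = as.integer(cl$np), nt = as.integer(cl$nt),
           ap = as.integer(cl$ap), am = as.integer(cl$am))
    }),
    strands = lapply(d$strands, function(s) {
      if (!s$alive) return(list(alive = FALSE))
      list(alive = TRUE, room = as.integer(s$room), folded = s$folded,
           rep_bound = s$rep_bound, busy = s$busy_rep,
           seq = as.integer(s$seq),
           atts = lapply(s$atts, function(a) {
             list(start = as.integer(a$start),
                  ligated = isTRUE(a$ligated),
                  seq = as.integer(a$seq),
                  ok = as.integer(a$ok), paired = as.integer(a$paired))
           }))
    }))
}

normalize_oracle <- function(st) {
  m <- unname(st$nt)
  storage.mode(m) <- "integer"
  list(
    np = as.integer(st$np), nt = m, ap = as.integer(st$ap),
    am = as.integer(st$am), cell = as.integer(st$cellid),
    cells = lapply(st$cells, function(cl) {
      list(alive = cl$alive, room = as.integer(cl$room), b = as.integer(cl$b),
           np = as.integer(cl$np), nt = as.integer(cl$nt),
           ap = as.integer(cl$ap), am = as.integer(cl$am))
    }),
    strands = lapply(st$strands, function(s) {
      if (!s$alive) return(list(alive = FALSE))
      list(alive = TRUE, room = as.integer(s$room), folded = s$folded,
           rep_bound = s$rep_bound, busy = s$busy,
           seq = as.integer(s$seq),
           atts = lapply(s$atts, function(a) {
             list(start = as.integer(a$start),
                  ligated = isTRUE(a$ligated),
                  seq = as.integer(a$seq),
                  ok = as.integer(a$ok), paired = as.integer(a$paired))
           }))
    }))
}
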