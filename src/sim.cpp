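// Monte-Carlo engine for nucleotide/amphiphile-resolution RNA-world evolution.
//
// All randomness flows through R's RNG (unif_rand / R::rbinom), so a run is
// fully determined by set.seed() on the R side, and an independent R
// implementation making the same draws in the same order reproduces the
// trajectory bit for bit.  The draw discipline (who draws, in which order,
// and when a draw is skipped) is part of the engine contract:
//   * counts draw rbinom(n, p) only when n > 0 and 0 < p < 1
//     (p <= 0 -> 0 events, p >= 1 -> n events, no draw);
//   * uniform choices among k options draw one unif_rand (floor(u*k));
//   * k movers split among t targets via t-1 sequential rbinom draws
//     (skipped as soon as the remainder is 0);
//   * entities iterate in stable creation order, rooms in row-major order;
//   * entities created during a phase do not participate in it.
//
// Base encoding: A=0, U=1, C=2, G=3; complement is b XOR 1 for A/U and
// b XOR 1 for C/G (i.e. 0<->1, 2<->3).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double U() { return unif_rand(); }

// Binomial draw.  For small expected counts an exact single-uniform
// inversion walk is used (cheap and replayable with one runif draw); larger
// cases fall back to R's rbinom.  The rule (inversion iff
// n*min(p,1-p) <= 10) is part of the draw-discipline contract.
static inline long binv_walk(long n, double p, double u) {
  double r = p / (1.0 - p);
  double pmf = std::exp((double) n * std::log1p(-p));
  double cum = pmf;
  long k = 0;
  while (u > cum && k < n) {
    pmf = pmf * (r * (double) (n - k) / (double) (k + 1));
    k += 1;
    cum = cum + pmf;
  }
  return k;
}

static inline long Bin(long n, double p) {
  if (n <= 0 || p <= 0) return 0;
  if (p >= 1) return n;
  double pm = p < 0.5 ? p : 1.0 - p;
  if ((double) n * pm <= 10.0) {
    double u = unif_rand();
    if (p <= 0.5) return binv_walk(n, p, u);
    return n - binv_walk(n, 1.0 - p, u);
  }
  return (long) R::rbinom((double) n, p);
}

static inline int pick(int k) {  // uniform 0..k-1, one draw
  int i = (int) (U() * k);
  return i >= k ? k - 1 : i;
}

static inline int comp_base(int b) { return b ^ 1; }  // A<->U, C<->G

static inline bool pair_wc(int x, int y) { return (x ^ 1) == y; }

static inline bool pair_wobble(int x, int y) {
  return pair_wc(x, y) || (x == 3 && y == 1) || (x == 1 && y == 3);
}

// ---- model structures -------------------------------------------------------

enum { CL_REP = 1, CL_NSR = 2, CL_ASR = 4, CL_CONTROL = 8 };
enum { ST_NAKED = 0, ST_PSEUDO = 1, ST_TRUE = 2 };

struct Params {
  double p_ad, p_adm, p_af, p_afr, p_ajm, p_alm, p_app, p_at, p_bb, p_cb,
      p_cd, p_cf, p_flr, p_fp, p_mc, p_mf, p_mv, p_nd, p_nde, p_nf, p_nfr,
      p_npp, p_rb, p_rd, p_rl, p_rtt, p_sp, p_tl, p_tlr;
  int N;
  double t_npb, t_apb;
  long l_am;
  double f_op, f_si, f_bo;
  int stage;
  bool refold, outward_perm, outside_rna_moves;
  int attract_mode;  // 0 flux, 1 extension, 2 template (bulk), 3 site
  int sep_mode;      // 0 processive, 1 memoryless, 2 ratchet
  int mform;  // 0 saturating, 1 constant
  bool has_ov[4];
  double ov_rtt[4];
};

struct Dom {
  int stem;
  int dlen;
  std::vector<int> loops[4];
};

struct Att {
  int start;
  bool ligated = false;         // a composite joined on the template
  std::vector<uint8_t> seq;     // actual bases, aligned to template positions
  std::vector<uint8_t> ok;      // complementary pairing at each site?
  std::vector<uint8_t> paired;  // base pair still intact?
};

struct Strand {
  bool alive = true;
  int room = 0;
  bool folded = true;
  bool rep_bound = false;  // a Rep is bound to this template
  int bound_rep = -1;
  bool busy_rep = false;   // this strand is a Rep serving a template
  int bound_tmpl = -1;
  int cls = 0;
  std::vector<uint8_t> seq;
  std::vector<Att> atts;   // sorted by start
};

struct Cell {
  bool alive = true;
  int room = 0;
  long b = 0;
  long np = 0, nt[4] = {0, 0, 0, 0}, ap = 0, am = 0;
};

struct Room {
  long np = 0, nt[4] = {0, 0, 0, 0}, ap = 0, am = 0;
  int cell = -1;
};

struct Sim {
  Params P;
  Dom D;
  int N, R;
  long step = 0;
  long long base_nt = 0, base_am = 0;  // conserved-unit baselines
  std::vector<Room> rooms;
  std::vector<Cell> cells;
  std::vector<Strand> strands;
  // reusable scratch (never part of the model state)
  std::vector<std::vector<int>> scratch_rooms;
  std::vector<long> mv_snap[7], mv_delta[7];
  double sp_pow[65];
};

// pool of the compartment at room r (naked pool, or interior of its cell)
struct Pool {
  long *np, *nt, *ap, *am;
};
static Pool pool_at(Sim &S, int r) {
  if (S.rooms[r].cell >= 0) {
    Cell &c = S.cells[S.rooms[r].cell];
    return {&c.np, c.nt, &c.ap, &c.am};
  }
  Room &rm = S.rooms[r];
  return {&rm.np, rm.nt, &rm.ap, &rm.am};
}

// neighbor order: up, down, left, right (toroidal)
static void neigh(const Sim &S, int r, int out[4]) {
  int N = S.N, row = r / N, col = r % N;
  out[0] = ((row - 1 + N) % N) * N + col;
  out[1] = ((row + 1) % N) * N + col;
  out[2] = row * N + (col - 1 + N) % N;
  out[3] = row * N + (col + 1) % N;
}

static void naked_neighbors(Sim &S, int r, std::vector<int> &out) {
  int nb[4];
  neigh(S, r, nb);
  out.clear();
  for (int d = 0; d < 4; ++d)
    if (nb[d] != r && S.rooms[nb[d]].cell < 0) out.push_back(nb[d]);
}

// ---- classification ---------------------------------------------------------

static int classify(const std::vector<uint8_t> &seq, const Dom &D) {
  int len = (int) seq.size();
  if (len < D.dlen || len >= 2 * D.dlen) return 0;
  int mask = 0;
  for (int s0 = 0; s0 + D.dlen <= len; ++s0) {
    // stem check shared by all loops
    bool stem = true;
    for (int i = 1; i <= D.stem && stem; ++i)
      if (!pair_wobble(seq[s0 + D.stem - i], seq[s0 + D.stem + 3 + i]))
        stem = false;
    if (!stem) continue;
    for (int c = 0; c < 4; ++c) {
      bool hit = true;
      for (int j = 0; j < 4; ++j)
        if (seq[s0 + D.stem + j] != D.loops[c][j]) { hit = false; break; }
      if (hit) mask |= (1 << c);
    }
  }
  return mask;
}

static void set_seq(Sim &S, Strand &s, std::vector<uint8_t> seq) {
  s.seq = std::move(seq);
  s.cls = classify(s.seq, S.D);
}

static double rtt_for(const Sim &S, const Strand &s) {
  for (int c = 0; c < 4; ++c)
    if (S.P.has_ov[c] && (s.cls & (1 << c))) return S.P.ov_rtt[c];
  return S.P.p_rtt;
}

static bool pool_eligible(const Strand &s) {
  return s.alive && s.folded && !s.busy_rep;
}

// RNA residues per room (strand bodies plus attached substrates)
static void residues_by_room(Sim &S, std::vector<long> &out) {
  out.assign(S.R, 0);
  for (auto &s : S.strands) {
    if (!s.alive) continue;
    long m = (long) s.seq.size();
    for (auto &a : s.atts) m += (long) a.seq.size();
    out[s.room] += m;
  }
}

static void totals(Sim &S, long long &nt_units, long long &am_units) {
  nt_units = 0;
  am_units = 0;
  for (int r = 0; r < S.R; ++r) {
    Room &rm = S.rooms[r];
    nt_units += rm.np + rm.nt[0] + rm.nt[1] + rm.nt[2] + rm.nt[3];
    am_units += rm.ap + rm.am;
  }
  for (auto &c : S.cells) {
    if (!c.alive) continue;
    nt_units += c.np + c.nt[0] + c.nt[1] + c.nt[2] + c.nt[3];
    am_units += c.ap + c.am + c.b;
  }
  for (auto &s : S.strands) {
    if (!s.alive) continue;
    nt_units += (long long) s.seq.size();
    for (auto &a : s.atts) nt_units += (long long) a.seq.size();
  }
}

static void rebaseline(Sim &S) { totals(S, S.base_nt, S.base_am); }

// strand ids bucketed by room, in id order (buffer reused across phases)
static std::vector<std::vector<int>> &bucket_by_room(Sim &S, bool only_pool) {
  auto &by_room = S.scratch_rooms;
  if ((int) by_room.size() != S.R) by_room.resize(S.R);
  for (auto &v : by_room) v.clear();
  for (size_t i = 0; i < S.strands.size(); ++i) {
    Strand &s = S.strands[i];
    if (!s.alive) continue;
    if (only_pool && !pool_eligible(s)) continue;
    by_room[s.room].push_back((int) i);
  }
  return by_room;
}

static void presence(Sim &S, int clbit, std::vector<char> &out) {
  out.assign(S.R, 0);
  for (auto &s : S.strands)
    if (s.alive && s.folded && !s.busy_rep && (s.cls & clbit)) out[s.room] = 1;
}

// ---- phase 1: nucleotide turnover ------------------------------------------

static void phase_nt_turnover(Sim &S) {
  std::vector<char> nsr;
  presence(S, CL_NSR, nsr);
  for (int r = 0; r < S.R; ++r) {
    Pool p = pool_at(S, r);
    if (*p.np > 0) {
      double pr = nsr[r] ? S.P.p_nfr : S.P.p_nf;
      long k = Bin(*p.np, pr);
      *p.np -= k;
      for (long j = 0; j < k; ++j) p.nt[pick(4)]++;
    }
    for (int b = 0; b < 4; ++b) {
      if (p.nt[b] > 0) {
        long d = Bin(p.nt[b], S.P.p_nd);
        p.nt[b] -= d;
        *p.np += d;
      }
    }
  }
}

// ---- phase 2: amphiphile turnover (incl. membrane decay) --------------------

static void phase_am_turnover(Sim &S) {
  if (S.P.stage == ST_NAKED) return;
  std::vector<char> asr;
  presence(S, CL_ASR, asr);
  std::vector<int> nn;
  for (int r = 0; r < S.R; ++r) {
    Pool p = pool_at(S, r);
    if (*p.ap > 0) {
      double pr = (S.P.stage == ST_TRUE && asr[r]) ? S.P.p_afr : S.P.p_af;
      long k = Bin(*p.ap, pr);
      *p.ap -= k;
      *p.am += k;
    }
    if (*p.am > 0) {
      long d = Bin(*p.am, S.P.p_ad);
      *p.am -= d;
      *p.ap += d;
    }
    int ci = S.rooms[r].cell;
    if (ci >= 0 && S.cells[ci].b > 0) {
      // membrane decay products are released to the exterior bath; if no
      // naked neighbor exists the decay is suppressed this step
      naked_neighbors(S, r, nn);
      if (!nn.empty()) {
        long d = Bin(S.cells[ci].b, S.P.p_adm);
        S.cells[ci].b -= d;
        for (long j = 0; j < d; ++j)
          S.rooms[nn[pick((int) nn.size())]].ap++;
      }
    }
  }
}

// ---- phase 3: strand end decay and bond breakage ----------------------------
//
// End decay and bond breakage are rare per-residue events, so they are drawn
// by exact aggregation: one binomial for the number of events over all
// eligible ends/bonds, then uniform draws (rejecting repeats) locate each
// event.  This is distributionally identical to independent per-site
// Bernoulli draws.  Duplex-engaged strands (templates with attachments or a
// bound Rep, and Reps serving a template) are protected by their pairing.

static void phase_strand_decay(Sim &S) {
  size_t n0 = S.strands.size();
  std::vector<int> elig;
  elig.reserve(n0);
  for (size_t i = 0; i < n0; ++i) {
    Strand &s = S.strands[i];
    if (s.alive && !s.busy_rep && !s.rep_bound && s.atts.empty())
      elig.push_back((int) i);
  }
  long ne = (long) elig.size();
  if (ne == 0) return;

  // which chain ends decay (end index e: strand elig[e/2], front if e%2==0)
  std::vector<char> d_front(ne, 0), d_back(ne, 0);
  long ke = Bin(2 * ne, S.P.p_nde);
  long placed = 0;
  while (placed < ke) {
    long e = (long) (U() * (2 * ne));
    if (e >= 2 * ne) e = 2 * ne - 1;
    char &flag = (e % 2 == 0) ? d_front[e / 2] : d_back[e / 2];
    if (!flag) { flag = 1; ++placed; }
  }

  // which internal bonds break: two rate groups (inside a protocell or in
  // the naked stage vs outside, where breakage is multiplied by F_BO);
  // bonds are counted on the end-trimmed chains
  std::vector<long> cum_in, cum_out;
  std::vector<int> ids_in, ids_out;
  long tot_in = 0, tot_out = 0;
  bool split_rates = (S.P.stage != ST_NAKED && S.P.f_bo != 1.0);
  for (long t = 0; t < ne; ++t) {
    Strand &s = S.strands[elig[t]];
    long nb = (long) s.seq.size() - 1 - (d_front[t] ? 1 : 0) -
              (d_back[t] ? 1 : 0);
    if (nb <= 0) continue;
    bool outside = S.rooms[s.room].cell < 0;
    if (split_rates && outside) {
      tot_out += nb;
      cum_out.push_back(tot_out);
      ids_out.push_back((int) t);
    } else {
      tot_in += nb;
      cum_in.push_back(tot_in);
      ids_in.push_back((int) t);
    }
  }
  std::vector<std::vector<int>> cuts(ne);  // bond j joins residues j-1 and j
  auto draw_group = [&](std::vector<long> &cum, std::vector<int> &ids,
                        long tot, double p) {
    long kb = Bin(tot, p);
    long done = 0;
    while (done < kb) {
      long g = (long) (U() * tot);
      if (g >= tot) g = tot - 1;
      size_t lo = std::lower_bound(cum.begin(), cum.end(), g + 1) - cum.begin();
      int t = ids[lo];
      long before = lo == 0 ? 0 : cum[lo - 1];
      int j = (int) (g - before) + 1;  // bond index on the trimmed chain
      auto &cv = cuts[t];
      if (std::find(cv.begin(), cv.end(), j) == cv.end()) {
        cv.push_back(j);
        ++done;
      }
    }
  };
  draw_group(cum_in, ids_in, tot_in, S.P.p_bb);
  if (split_rates) draw_group(cum_out, ids_out, tot_out, S.P.p_bb * S.P.f_bo);

  // apply trims and cuts per strand
  for (long t = 0; t < ne; ++t) {
    if (!d_front[t] && !d_back[t] && cuts[t].empty()) continue;
    int i = elig[t];
    int room = S.strands[i].room;
    Pool p = pool_at(S, room);
    std::vector<uint8_t> seq = S.strands[i].seq;
    if (d_back[t]) { seq.pop_back(); *p.np += 1; }
    if (d_front[t]) {
      if (!seq.empty()) seq.erase(seq.begin());
      *p.np += 1;
    }
    if (seq.empty()) { S.strands[i].alive = false; continue; }
    if (seq.size() == 1) {
      p.nt[seq[0]]++;
      S.strands[i].alive = false;
      continue;
    }
    std::vector<int> cv = cuts[t];
    std::sort(cv.begin(), cv.end());
    cv.push_back((int) seq.size());
    std::vector<std::vector<uint8_t>> frags;
    int from = 0;
    for (int cut : cv) {
      if (cut > (int) seq.size()) cut = (int) seq.size();
      if (cut <= from) continue;
      std::vector<uint8_t> frag(seq.begin() + from, seq.begin() + cut);
      from = cut;
      if (frag.size() == 1) p.nt[frag[0]]++;
      else frags.push_back(std::move(frag));
    }
    // first multi-residue fragment keeps this strand record; the rest are
    // appended (push_back may reallocate, so no references are held across)
    if (frags.empty()) {
      S.strands[i].alive = false;
    } else {
      set_seq(S, S.strands[i], frags[0]);
      for (size_t f = 1; f < frags.size(); ++f) {
        Strand ns;
        ns.room = room;
        S.strands.push_back(ns);
        set_seq(S, S.strands.back(), frags[f]);
      }
    }
  }
}

// ---- phase 4: random end-to-end ligation ------------------------------------

static void phase_random_ligation(Sim &S) {
  auto &by_room = bucket_by_room(S, true);  // snapshot: new strands excluded
  for (int r = 0; r < S.R; ++r) {
    Pool p = pool_at(S, r);
    long ntot = p.nt[0] + p.nt[1] + p.nt[2] + p.nt[3];
    if (ntot <= 0) continue;
    long k = Bin(ntot, S.P.p_rl);
    for (long ev = 0; ev < k; ++ev) {
      ntot = p.nt[0] + p.nt[1] + p.nt[2] + p.nt[3];
      if (ntot <= 0) break;
      // pick the ligating nucleotide, weighted by the per-base pool
      double u = U() * ntot;
      int base = 0;
      long cum = 0;
      for (int b = 0; b < 4; ++b) {
        cum += p.nt[b];
        if (u < cum) { base = b; break; }
      }
      // partner: any other free nucleotide, or either end of a free strand
      std::vector<int> elig;
      for (int sid : by_room[r])
        if (pool_eligible(S.strands[sid])) elig.push_back(sid);
      long m = (ntot - 1) + 2 * (long) elig.size();
      if (m <= 0) continue;
      long pi = (long) (U() * m);
      if (pi >= m) pi = m - 1;
      if (pi < ntot - 1) {
        // nucleotide partner, weighted by the pool minus the first pick
        long w[4] = {p.nt[0], p.nt[1], p.nt[2], p.nt[3]};
        w[base] -= 1;
        double u2 = U() * (ntot - 1);
        int b2 = 0;
        long c2 = 0;
        for (int b = 0; b < 4; ++b) {
          c2 += w[b];
          if (u2 < c2) { b2 = b; break; }
        }
        p.nt[base]--;
        p.nt[b2]--;
        Strand ns;
        ns.room = r;
        S.strands.push_back(ns);
        set_seq(S, S.strands.back(), {(uint8_t) base, (uint8_t) b2});
      } else {
        long si = (pi - (ntot - 1)) / 2;
        int end = (int) ((pi - (ntot - 1)) % 2);  // 0 = front, 1 = back
        Strand &t = S.strands[elig[si]];
        p.nt[base]--;
        std::vector<uint8_t> seq = t.seq;
        if (end == 0) seq.insert(seq.begin(), (uint8_t) base);
        else seq.push_back((uint8_t) base);
        set_seq(S, t, seq);
      }
    }
  }
}

// ---- phase 5: template dynamics --------------------------------------------

static void phase_template_state(Sim &S) {
  size_t n0 = S.strands.size();
  for (size_t i = 0; i < n0; ++i) {
    Strand &s = S.strands[i];
    if (!s.alive || s.busy_rep || s.rep_bound || !s.atts.empty()) continue;
    double prt = rtt_for(S, s);
    if (s.folded) {
      if (U() < prt) s.folded = false;
    } else if (S.P.refold) {
      if (U() < 1.0 - prt) s.folded = true;
    }
  }
}

// A free folded Rep molecule binds one template at a time (it is marked
// occupied while serving) and drops with P_RD.  Because the state-flip
// phase runs before binding each step, a Rep released or refolded in one
// step still gets its own chance to unfold and be copied in the next.
static void phase_rep_bind(Sim &S) {
  auto &rep_room = S.scratch_rooms;
  if ((int) rep_room.size() != S.R) rep_room.resize(S.R);
  for (auto &v : rep_room) v.clear();
  for (size_t i = 0; i < S.strands.size(); ++i) {
    Strand &s = S.strands[i];
    if (s.alive && s.folded && !s.busy_rep && (s.cls & CL_REP))
      rep_room[s.room].push_back((int) i);
  }
  size_t n0 = S.strands.size();
  std::vector<int> reps;
  for (size_t i = 0; i < n0; ++i) {
    Strand &s = S.strands[i];
    if (!s.alive || s.folded) continue;  // templates only
    if (s.rep_bound) {
      if (U() < S.P.p_rd) {
        Strand &rep = S.strands[s.bound_rep];
        rep.busy_rep = false;
        rep.bound_tmpl = -1;
        s.rep_bound = false;
        s.bound_rep = -1;
      }
    } else {
      if (rep_room[s.room].empty()) continue;
      reps.clear();
      for (int sid : rep_room[s.room])
        if (!S.strands[sid].busy_rep) reps.push_back(sid);
      if (reps.empty()) continue;
      if (U() < S.P.p_rb) {
        int rid = reps[pick((int) reps.size())];
        s.rep_bound = true;
        s.bound_rep = rid;
        S.strands[rid].busy_rep = true;
        S.strands[rid].bound_tmpl = (int) i;
      }
    }
  }
}

// Substrate attraction.  Default ("template"): a template attracts with
// P_AT per step; on success every currently uncovered site is loaded in a
// left-to-right sweep, each site drawing its candidate substrate (free
// nucleotide, or a fitting free oligomer placed starting at the site)
// uniformly, so one event can cover the template while fidelity stays
// per-residue.  Alternative ("site"): each uncovered site independently
// attracts one arrival with P_AT per step.  A nucleotide takes the
// complementary base with probability 1-P_FP, otherwise one of the three
// non-complementary bases uniformly; an oligomer must pair (or pass an
// independent P_FP draw) at every residue, reading antiparallel to the
// template.  Either way a site may stay empty when the drawn substrate is
// unavailable or fails its pairing test.

// one site-filling attempt; fills the site at pos (align_end = false,
// oligomers extend rightward) or the site at pos with oligomers ending
// there (align_end = true); returns the next uncovered position
static int attract_at(Sim &S, Strand &s, Pool &p,
                      std::vector<std::vector<int>> &by_room, int pos,
                      int stretch_start, int stretch_end, bool align_end) {
  long ntot = p.nt[0] + p.nt[1] + p.nt[2] + p.nt[3];
  std::vector<int> oligs;
  for (int sid : by_room[s.room]) {
    Strand &o = S.strands[sid];
    if (!pool_eligible(o)) continue;
    int L = (int) o.seq.size();
    bool fits = align_end ? (pos - L + 1 >= stretch_start)
                          : (pos + L - 1 <= stretch_end);
    if (fits) oligs.push_back(sid);
  }
  long c = ntot + (long) oligs.size();
  if (c <= 0) return pos + 1;
  long ci = (long) (U() * c);
  if (ci >= c) ci = c - 1;
  if (ci < ntot) {
    int tb = s.seq[pos];
    int base, okf;
    if (U() < 1.0 - S.P.p_fp) {
      base = comp_base(tb);
      okf = 1;
    } else {
      int alt = pick(3);
      base = 0;
      for (int b = 0, seen = 0; b < 4; ++b) {
        if (b == comp_base(tb)) continue;
        if (seen == alt) { base = b; break; }
        ++seen;
      }
      okf = 0;
    }
    if (p.nt[base] <= 0) return pos + 1;  // substrate unavailable
    p.nt[base]--;
    Att a;
    a.start = pos;
    a.seq = {(uint8_t) base};
    a.ok = {(uint8_t) okf};
    a.paired = {1};
    auto it = s.atts.begin();
    while (it != s.atts.end() && it->start < pos) ++it;
    s.atts.insert(it, a);
    return pos + 1;
  }
  Strand &o = S.strands[oligs[ci - ntot]];
  int L = (int) o.seq.size();
  int start = align_end ? pos - L + 1 : pos;
  std::vector<uint8_t> al(o.seq.rbegin(), o.seq.rend());
  std::vector<uint8_t> ok(L, 0);
  for (int j = 0; j < L; ++j) {
    if (pair_wc(al[j], s.seq[start + j])) {
      ok[j] = 1;
    } else if (U() < S.P.p_fp) {
      ok[j] = 0;
    } else {
      return pos + 1;  // attachment fails as a whole
    }
  }
  o.alive = false;
  Att a;
  a.start = start;
  a.seq = al;
  a.ok = ok;
  a.paired.assign(L, 1);
  auto it = s.atts.begin();
  while (it != s.atts.end() && it->start < start) ++it;
  s.atts.insert(it, a);
  return start + L;
}

// Flux attraction ("flux", default): attachment events arrive at the rate
// of the compartment's free substrates -- each free nucleotide or oligomer
// is attracted with P_AT per step -- so rooms rich in building blocks
// replicate proportionally faster (the metabolic coupling through Nsr).
// Each event picks a growth site uniformly among the templates' uncovered
// stretches (a stretch offers the site flanking an existing attachment,
// left flank preferred, or a uniform position on a bare template), then a
// substrate uniformly.  Fidelity is per residue as in the other modes.
struct GrowthSite {
  int tmpl;       // strand id
  int pos;        // site to fill
  int a0, b0;     // containing stretch
  bool align_end; // oligomers end at pos instead of starting there
  bool bare;      // uniform-position nucleation site
};

static void growth_sites(Sim &S, std::vector<int> &tmpls,
                         std::vector<GrowthSite> &out) {
  out.clear();
  for (int ti : tmpls) {
    Strand &s = S.strands[ti];
    if (!s.alive || s.folded) continue;
    int len = (int) s.seq.size();
    int cur = 0;
    for (size_t ai = 0; ai <= s.atts.size(); ++ai) {
      int upto = ai < s.atts.size() ? s.atts[ai].start : len;
      if (upto > cur) {
        GrowthSite g;
        g.tmpl = ti;
        g.a0 = cur;
        g.b0 = upto - 1;
        bool left_flank = cur > 0;
        bool right_flank = upto < len;
        if (left_flank) {
          g.pos = g.a0;
          g.align_end = false;
          g.bare = false;
        } else if (right_flank) {
          g.pos = g.b0;
          g.align_end = true;
          g.bare = false;
        } else {
          g.pos = -1;  // uniform draw at use
          g.align_end = false;
          g.bare = true;
        }
        out.push_back(g);
      }
      if (ai < s.atts.size()) cur = s.atts[ai].start + (int) s.atts[ai].seq.size();
    }
  }
}

static void phase_attraction_flux(Sim &S,
                                  std::vector<std::vector<int>> &by_room) {
  std::vector<GrowthSite> sites, fresh;
  std::vector<int> one;
  for (int r = 0; r < S.R; ++r) {
    if (by_room[r].empty()) continue;
    // any template with uncovered sites?
    growth_sites(S, by_room[r], sites);
    if (sites.empty()) continue;
    Pool p = pool_at(S, r);
    long ntot = p.nt[0] + p.nt[1] + p.nt[2] + p.nt[3];
    long S0 = ntot;
    for (int sid : by_room[r])
      if (pool_eligible(S.strands[sid])) ++S0;
    if (S0 <= 0) continue;
    long k = Bin(S0, S.P.p_at);
    for (long ev = 0; ev < k; ++ev) {
      if (sites.empty()) break;
      GrowthSite g = sites[pick((int) sites.size())];
      int pos = g.pos;
      if (g.bare) pos = g.a0 + pick(g.b0 - g.a0 + 1);
      attract_at(S, S.strands[g.tmpl], p, by_room, pos, g.a0, g.b0,
                 g.align_end);
      // refresh only the touched template's entries: drop its old sites
      // (order preserved) and append its recomputed ones at the end
      sites.erase(std::remove_if(sites.begin(), sites.end(),
                                 [&](const GrowthSite &x) {
                                   return x.tmpl == g.tmpl;
                                 }),
                  sites.end());
      one.assign(1, g.tmpl);
      growth_sites(S, one, fresh);
      sites.insert(sites.end(), fresh.begin(), fresh.end());
    }
  }
}

static void phase_attraction(Sim &S) {
  auto &by_room = bucket_by_room(S, false);  // snapshot of all strands by room
  size_t n0 = S.strands.size();
  std::vector<int> unc, oligs;
  std::vector<std::pair<int, int>> stretches;
  if (S.P.attract_mode == 0) {
    phase_attraction_flux(S, by_room);
    return;
  }
  for (size_t i = 0; i < n0; ++i) {
    if (!S.strands[i].alive || S.strands[i].folded) continue;
    if (S.P.attract_mode == 1) {
      // contiguous extension: one attempt per uncovered stretch per step,
      // placed against a flanking attachment when one exists (left flank
      // preferred), else at a uniform position; runs therefore grow
      // contiguously from a nucleation site
      Strand &s0 = S.strands[i];
      int len = (int) s0.seq.size();
      stretches.clear();
      int cur = 0;
      for (auto &a : s0.atts) {
        if (a.start > cur) stretches.push_back({cur, a.start - 1});
        cur = a.start + (int) a.seq.size();
      }
      if (cur < len) stretches.push_back({cur, len - 1});
      Pool p = pool_at(S, S.strands[i].room);
      for (auto &g : stretches) {
        if (U() >= S.P.p_at) continue;
        int a0 = g.first, b0 = g.second;
        bool left_flank = a0 > 0;
        bool right_flank = b0 < len - 1;
        if (left_flank) {
          attract_at(S, S.strands[i], p, by_room, a0, a0, b0, false);
        } else if (right_flank) {
          attract_at(S, S.strands[i], p, by_room, b0, a0, b0, true);
        } else {
          int pos = a0 + pick(b0 - a0 + 1);
          attract_at(S, S.strands[i], p, by_room, pos, a0, b0, false);
        }
      }
      continue;
    }
    if (S.P.attract_mode == 2) {
      Strand &s0 = S.strands[i];
      int len = (int) s0.seq.size();
      long cov = 0;
      for (auto &a : s0.atts) cov += (long) a.seq.size();
      if (cov >= len) continue;
      if (U() >= S.P.p_at) continue;
      // left-to-right sweep over the uncovered stretches as they were at
      // event time; placements advance the cursor past their coverage
      stretches.clear();
      int cur = 0;
      for (auto &a : s0.atts) {
        if (a.start > cur) stretches.push_back({cur, a.start - 1});
        cur = a.start + (int) a.seq.size();
      }
      if (cur < len) stretches.push_back({cur, len - 1});
      Pool p = pool_at(S, S.strands[i].room);
      for (auto &g : stretches) {
        int pos = g.first;
        while (pos <= g.second) {
          pos = attract_at(S, S.strands[i], p, by_room, pos, g.first,
                           g.second, false);
        }
      }
      continue;
    }
    {
      Strand &s = S.strands[i];
      int len = (int) s.seq.size();
      long cov = 0;
      for (auto &a : s.atts) cov += (long) a.seq.size();
      long k = Bin(len - cov, S.P.p_at);
      Pool p = pool_at(S, s.room);
      for (long ev = 0; ev < k; ++ev) {
        // uncovered sites under the current coverage
        unc.clear();
        int cur = 0;
        for (auto &a : s.atts) {
          for (int q = cur; q < a.start; ++q) unc.push_back(q);
          cur = a.start + (int) a.seq.size();
        }
        for (int q = cur; q < len; ++q) unc.push_back(q);
        if (unc.empty()) break;
        int pidx = pick((int) unc.size());
        int pos = unc[pidx];
        // maximal uncovered stretch [a0, b0] containing pos (unc is sorted)
        int ia = pidx, ib = pidx;
        while (ia > 0 && unc[ia - 1] == unc[ia] - 1) --ia;
        while (ib + 1 < (int) unc.size() && unc[ib + 1] == unc[ib] + 1) ++ib;
        int a0 = unc[ia], b0 = unc[ib];
        int glen = b0 - a0 + 1;
        long ntot = p.nt[0] + p.nt[1] + p.nt[2] + p.nt[3];
        oligs.clear();
        for (int sid : by_room[s.room]) {
          Strand &o = S.strands[sid];
          if (pool_eligible(o) && (int) o.seq.size() <= glen)
            oligs.push_back(sid);
        }
        long c = ntot + (long) oligs.size();
        if (c <= 0) continue;
        long ci = (long) (U() * c);
        if (ci >= c) ci = c - 1;
        if (ci < ntot) {
          int tb = s.seq[pos];
          int base, okf;
          if (U() < 1.0 - S.P.p_fp) {
            base = comp_base(tb);
            okf = 1;
          } else {
            // uniform over the three non-complementary bases, in AUCG order
            int alt = pick(3);
            base = 0;
            for (int b = 0, seen = 0; b < 4; ++b) {
              if (b == comp_base(tb)) continue;
              if (seen == alt) { base = b; break; }
              ++seen;
            }
            okf = 0;
          }
          if (p.nt[base] <= 0) continue;  // substrate unavailable
          p.nt[base]--;
          Att a;
          a.start = pos;
          a.seq = {(uint8_t) base};
          a.ok = {(uint8_t) okf};
          a.paired = {1};
          auto it = s.atts.begin();
          while (it != s.atts.end() && it->start < pos) ++it;
          s.atts.insert(it, a);
        } else {
          Strand &o = S.strands[oligs[ci - ntot]];
          int L = (int) o.seq.size();
          // uniform placement covering pos within the stretch
          int lo = std::max(a0, pos - L + 1);
          int hi = std::min(pos, b0 - L + 1);
          int start = lo + pick(hi - lo + 1);
          // antiparallel alignment: reversed oligomer pairs the template
          std::vector<uint8_t> al(o.seq.rbegin(), o.seq.rend());
          std::vector<uint8_t> ok(L, 0);
          bool fail = false;
          for (int j = 0; j < L; ++j) {
            if (pair_wc(al[j], s.seq[start + j])) {
              ok[j] = 1;
            } else if (U() < S.P.p_fp) {
              ok[j] = 0;
            } else {
              fail = true;
              break;
            }
          }
          if (fail) continue;
          o.alive = false;
          Att a;
          a.start = start;
          a.seq = al;
          a.ok = ok;
          a.paired.assign(L, 1);
          auto it = s.atts.begin();
          while (it != s.atts.end() && it->start < start) ++it;
          s.atts.insert(it, a);
        }
      }
    }
  }
}

static void phase_template_ligation(Sim &S) {
  size_t n0 = S.strands.size();
  for (size_t i = 0; i < n0; ++i) {
    Strand &s = S.strands[i];
    if (!s.alive || s.folded || s.atts.size() < 2) continue;
    size_t j = 0;
    while (j + 1 < s.atts.size()) {
      Att &a = s.atts[j];
      Att &b = s.atts[j + 1];
      if (a.start + (int) a.seq.size() != b.start) { ++j; continue; }
      double pr = s.rep_bound ? S.P.p_tlr : S.P.p_tl;
      bool go = U() < pr;
      if (go && s.rep_bound && (!a.ok.back() || !b.ok.front()))
        go = U() < S.P.p_flr;  // false flank gate (Rep-mediated only)
      if (go) {
        a.seq.insert(a.seq.end(), b.seq.begin(), b.seq.end());
        a.ok.insert(a.ok.end(), b.ok.begin(), b.ok.end());
        a.paired.insert(a.paired.end(), b.paired.begin(), b.paired.end());
        // only the replicase clamps the growing copy to the template; a
        // non-enzymatically joined chain remains an ordinary substrate
        if (s.rep_bound) a.ligated = true;
        s.atts.erase(s.atts.begin() + j + 1);
        // the junction with the next attachment is at the same index
      } else {
        ++j;
      }
    }
  }
}

// Dissociation.  Substrates (attachments never ligated on the template) and
// products can dissociate; a partial ligated run is a bound reaction
// intermediate and stays until elongation completes it.  Default
// ("processive"): an unligated substrate leaves when all of its pairs
// separate in the same step (probability P_SP^length); a ligated composite
// can leave -- at the same rate -- only once it covers the whole template,
// which is the replication product and the source of product inhibition.
// "memoryless" lets every attachment leave at P_SP^length; "ratchet" flips
// each pair permanently with P_SP and releases an attachment once every
// pair has separated.  A released single nucleotide returns to the free
// pool; a released chain becomes a folded strand reading antiparallel to
// the template.
static void phase_separation(Sim &S) {
  size_t n0 = S.strands.size();
  for (size_t i = 0; i < n0; ++i) {
    if (!S.strands[i].alive || S.strands[i].folded ||
        S.strands[i].atts.empty())
      continue;
    int room = S.strands[i].room;
    Pool p = pool_at(S, room);
    // push_back below may reallocate the strand vector, so the strand is
    // re-indexed at every use instead of held by reference
    for (size_t j = 0; j < S.strands[i].atts.size();) {
      bool rel;
      if (S.P.sep_mode == 2) {
        Att &a = S.strands[i].atts[j];
        bool any = false;
        for (size_t q = 0; q < a.seq.size(); ++q) {
          if (a.paired[q] && U() < S.P.p_sp) a.paired[q] = 0;
          if (a.paired[q]) any = true;
        }
        rel = !any;
      } else {
        Att &a = S.strands[i].atts[j];
        size_t len = a.seq.size();
        if (S.P.sep_mode == 0 && a.ligated &&
            len < S.strands[i].seq.size()) {
          rel = false;  // bound intermediate: no draw
        } else {
          double p_rel = len <= 64 ? S.sp_pow[len]
                                   : std::pow(S.P.p_sp, (double) len);
          rel = p_rel >= 1.0 ? true : (p_rel <= 0.0 ? false : U() < p_rel);
        }
      }
      if (rel) {
        Att a = S.strands[i].atts[j];
        S.strands[i].atts.erase(S.strands[i].atts.begin() + j);
        if (a.seq.size() == 1) {
          p.nt[a.seq[0]]++;
        } else {
          // released product reads antiparallel to the template
          std::vector<uint8_t> seq(a.seq.rbegin(), a.seq.rend());
          Strand ns;
          ns.room = room;
          S.strands.push_back(ns);
          set_seq(S, S.strands.back(), seq);
        }
      } else {
        ++j;
      }
    }
  }
}

// ---- phase 6: membranes -----------------------------------------------------

static double memb_form_p(const Sim &S, long a) {
  if (a < S.P.l_am) return 0.0;
  if (S.P.mform == 1) return S.P.p_mf;
  return S.P.p_mf * (1.0 - (double) S.P.l_am / (double) (a + 1));
}

static void phase_membranes(Sim &S) {
  if (S.P.stage == ST_NAKED) return;
  std::vector<int> nn;
  // 6a: membrane formation in naked rooms
  for (int r = 0; r < S.R; ++r) {
    if (S.rooms[r].cell >= 0) continue;
    Room &rm = S.rooms[r];
    double pf = memb_form_p(S, rm.am);
    if (pf <= 0) continue;
    if (U() < pf) {
      Cell c;
      c.room = r;
      c.b = rm.am;
      c.np = rm.np;
      for (int b = 0; b < 4; ++b) c.nt[b] = rm.nt[b];
      c.ap = rm.ap;
      c.am = 0;
      rm.np = rm.ap = rm.am = 0;
      for (int b = 0; b < 4; ++b) rm.nt[b] = 0;
      S.cells.push_back(c);
      rm.cell = (int) S.cells.size() - 1;
      // strands in the room are encompassed (interior = same room index)
    }
  }
  // interior impermeable units n = interior nucleotides + RNA residues;
  // strand contents do not change during this phase, so compute once
  std::vector<long> res_room;
  residues_by_room(S, res_room);
  // 6b: membrane exchange
  int nbr[4];
  for (int r = 0; r < S.R; ++r) {
    int ci = S.rooms[r].cell;
    if (ci < 0) continue;
    Cell &c = S.cells[ci];
    neigh(S, r, nbr);
    for (int d = 0; d < 4; ++d) {
      int q = nbr[d];
      if (q == r || S.rooms[q].cell >= 0) continue;
      if (S.rooms[q].am > 0) {
        long k = Bin(S.rooms[q].am, S.P.p_ajm);
        S.rooms[q].am -= k;
        c.b += k;
      }
    }
    if (c.am > 0) {  // interior amphiphiles also reach the membrane
      long k = Bin(c.am, S.P.p_ajm);
      c.am -= k;
      c.b += k;
    }
    if (c.b >= 2) {
      naked_neighbors(S, r, nn);
      if (!nn.empty()) {
        long n = c.nt[0] + c.nt[1] + c.nt[2] + c.nt[3] + res_room[r];
        double pl = S.P.p_alm /
                    (1.0 + S.P.f_op * (double) n / std::pow(c.b / 2.0, 1.5));
        long k = Bin(c.b, pl);
        c.b -= k;
        for (long j = 0; j < k; ++j) S.rooms[nn[pick((int) nn.size())]].am++;
      }
    }
  }
  // 6c: permeation
  for (int r = 0; r < S.R; ++r) {
    int ci = S.rooms[r].cell;
    if (ci < 0) continue;
    Cell &c = S.cells[ci];
    if (c.b < S.P.l_am) continue;  // crossing shut below the assembly limit
    long n = c.nt[0] + c.nt[1] + c.nt[2] + c.nt[3] + res_room[r];
    double shrink = std::pow((double) S.P.l_am / (double) c.b, 1.5);
    double pin_np = (1.0 - (1.0 - S.P.p_npp) * shrink) /
                    (1.0 + S.P.f_si * (double) n / std::pow(c.b / 2.0, 1.5));
    double pin_ap = 1.0 - (1.0 - S.P.p_app) * shrink;
    if (pin_np < 0) pin_np = 0;
    if (pin_ap < 0) pin_ap = 0;
    neigh(S, r, nbr);
    for (int d = 0; d < 4; ++d) {
      int q = nbr[d];
      if (q == r || S.rooms[q].cell >= 0) continue;
      if (S.rooms[q].np > 0) {
        long k = Bin(S.rooms[q].np, pin_np);
        S.rooms[q].np -= k;
        c.np += k;
      }
      if (S.rooms[q].ap > 0) {
        long k = Bin(S.rooms[q].ap, pin_ap);
        S.rooms[q].ap -= k;
        c.ap += k;
      }
    }
    if (S.P.outward_perm) {
      naked_neighbors(S, r, nn);
      if (!nn.empty()) {
        if (c.np > 0) {
          long k = Bin(c.np, pin_np);
          c.np -= k;
          for (long j = 0; j < k; ++j) S.rooms[nn[pick((int) nn.size())]].np++;
        }
        if (c.ap > 0) {
          long k = Bin(c.ap, pin_ap);
          c.ap -= k;
          for (long j = 0; j < k; ++j) S.rooms[nn[pick((int) nn.size())]].ap++;
        }
      }
    }
  }
}

// ---- phase 7: protocell break / fuse / divide -------------------------------

static void do_break(Sim &S, int ci) {
  Cell &c = S.cells[ci];
  Room &rm = S.rooms[c.room];
  rm.np += c.np;
  for (int b = 0; b < 4; ++b) rm.nt[b] += c.nt[b];
  rm.ap += c.ap;
  rm.am += c.am + c.b;
  rm.cell = -1;
  c.alive = false;
  // interior strands simply become free strands of the now-naked room
}

static void phase_cells(Sim &S) {
  if (S.P.stage == ST_NAKED) return;
  // 7a: break (forced below the two-amphiphile minimum)
  std::vector<int> order;
  for (int r = 0; r < S.R; ++r)
    if (S.rooms[r].cell >= 0) order.push_back(S.rooms[r].cell);
  for (int ci : order) {
    Cell &c = S.cells[ci];
    if (!c.alive) continue;
    if (c.b < 2) { do_break(S, ci); continue; }
    if (U() < S.P.p_cb) do_break(S, ci);
  }
  // 7b: fusion of adjacent pairs; each shared edge is enumerated once via
  // the down/right neighbor of each room (on a torus of side >= 3 this
  // lists every unordered pair exactly once)
  int nbr[4];
  for (int r = 0; r < S.R; ++r) {
    if (S.rooms[r].cell < 0) continue;
    neigh(S, r, nbr);
    int cand[2] = {nbr[1], nbr[3]};  // down, right
    for (int t = 0; t < 2; ++t) {
      int q = cand[t];
      if (q == r || S.rooms[r].cell < 0 || S.rooms[q].cell < 0) continue;
      if (U() >= S.P.p_cf) continue;
      int ca = S.rooms[r].cell, cb = S.rooms[q].cell;
      bool keep_a = U() < 0.5;
      int keep = keep_a ? ca : cb, gone = keep_a ? cb : ca;
      int room_gone = S.cells[gone].room;
      Cell &K = S.cells[keep];
      Cell &G = S.cells[gone];
      K.b += G.b;
      K.np += G.np;
      for (int b = 0; b < 4; ++b) K.nt[b] += G.nt[b];
      K.ap += G.ap;
      K.am += G.am;
      for (auto &s : S.strands)
        if (s.alive && s.room == room_gone) s.room = K.room;
      S.rooms[room_gone].cell = -1;
      G.alive = false;
    }
  }
  // 7c: division
  order.clear();
  for (int r = 0; r < S.R; ++r)
    if (S.rooms[r].cell >= 0 && S.cells[S.rooms[r].cell].alive)
      order.push_back(S.rooms[r].cell);
  std::vector<int> nn, push_to;
  for (int ci : order) {
    Cell &c = S.cells[ci];
    if (!c.alive || c.b < 2) continue;
    double pd = S.P.p_cd * (1.0 - 2.0 * (double) S.P.l_am / (double) c.b);
    if (pd <= 0) continue;
    if (U() >= pd) continue;
    naked_neighbors(S, c.room, nn);
    if (nn.empty()) continue;  // fails silently
    int target = nn[pick((int) nn.size())];
    // random partition of membrane and contents
    long b_stay = Bin(c.b, 0.5);
    long np_stay = Bin(c.np, 0.5);
    long nt_stay[4];
    for (int b = 0; b < 4; ++b) nt_stay[b] = Bin(c.nt[b], 0.5);
    long ap_stay = Bin(c.ap, 0.5);
    long am_stay = Bin(c.am, 0.5);
    std::vector<int> movers;
    for (size_t i = 0; i < S.strands.size(); ++i) {
      Strand &s = S.strands[i];
      if (!s.alive || s.room != c.room) continue;
      if (s.busy_rep) continue;  // follows its template
      bool stays = U() < 0.5;
      if (!stays) {
        movers.push_back((int) i);
        if (s.rep_bound) movers.push_back(s.bound_rep);
      }
    }
    // push the target room's free contents to its other naked neighbors;
    // with none available they are engulfed by the arriving offspring
    naked_neighbors(S, target, push_to);
    push_to.erase(std::remove(push_to.begin(), push_to.end(), target),
                  push_to.end());
    Room &T = S.rooms[target];
    Cell nc;
    nc.room = target;
    nc.b = c.b - b_stay;
    nc.np = c.np - np_stay;
    for (int b = 0; b < 4; ++b) nc.nt[b] = c.nt[b] - nt_stay[b];
    nc.ap = c.ap - ap_stay;
    nc.am = c.am - am_stay;
    c.b = b_stay;
    c.np = np_stay;
    for (int b = 0; b < 4; ++b) c.nt[b] = nt_stay[b];
    c.ap = ap_stay;
    c.am = am_stay;
    if (!push_to.empty()) {
      for (long j = 0; j < T.np; ++j) S.rooms[push_to[pick((int) push_to.size())]].np++;
      for (int b = 0; b < 4; ++b)
        for (long j = 0; j < T.nt[b]; ++j)
          S.rooms[push_to[pick((int) push_to.size())]].nt[b]++;
      for (long j = 0; j < T.ap; ++j) S.rooms[push_to[pick((int) push_to.size())]].ap++;
      for (long j = 0; j < T.am; ++j) S.rooms[push_to[pick((int) push_to.size())]].am++;
      T.np = T.ap = T.am = 0;
      for (int b = 0; b < 4; ++b) T.nt[b] = 0;
      for (auto &s : S.strands)
        if (s.alive && s.room == target)
          s.room = push_to[pick((int) push_to.size())];
    } else {
      nc.np += T.np;
      for (int b = 0; b < 4; ++b) nc.nt[b] += T.nt[b];
      nc.ap += T.ap;
      nc.am += T.am;
      T.np = T.ap = T.am = 0;
      for (int b = 0; b < 4; ++b) T.nt[b] = 0;
      // free strands in the target room become interior (engulfed)
    }
    S.cells.push_back(nc);
    S.rooms[target].cell = (int) S.cells.size() - 1;
    for (int id : movers) S.strands[id].room = target;
  }
}

// ---- phase 8: movement ------------------------------------------------------

static void move_counts(Sim &S, long *live, std::vector<long> &delta, int r,
                        const std::vector<int> &nn, long snap, double p) {
  if (snap <= 0) return;
  long k = Bin(snap, p);
  if (k <= 0) return;
  *live -= k;
  long rem = k;
  int t = (int) nn.size();
  for (int i = 0; i < t - 1 && rem > 0; ++i) {
    long ki = Bin(rem, 1.0 / (t - i));
    delta[nn[i]] += ki;
    rem -= ki;
  }
  delta[nn[t - 1]] += rem;
}

static void phase_movement(Sim &S) {
  bool naked_stage = (S.P.stage == ST_NAKED);
  bool rna_moves = naked_stage || S.P.outside_rna_moves;
  // 8a: free molecules between naked rooms (snapshot then apply deltas so
  // arrivals are never re-drawn within the phase)
  auto &snp = S.mv_snap[0];
  auto &sap = S.mv_snap[5];
  auto &sam = S.mv_snap[6];
  auto &dnp = S.mv_delta[0];
  auto &dap = S.mv_delta[5];
  auto &dam = S.mv_delta[6];
  std::vector<long> *snt[4] = {&S.mv_snap[1], &S.mv_snap[2], &S.mv_snap[3],
                               &S.mv_snap[4]};
  std::vector<long> *dnt[4] = {&S.mv_delta[1], &S.mv_delta[2], &S.mv_delta[3],
                               &S.mv_delta[4]};
  snp.assign(S.R, 0); sap.assign(S.R, 0); sam.assign(S.R, 0);
  dnp.assign(S.R, 0); dap.assign(S.R, 0); dam.assign(S.R, 0);
  for (int b = 0; b < 4; ++b) {
    snt[b]->assign(S.R, 0);
    dnt[b]->assign(S.R, 0);
  }
  for (int r = 0; r < S.R; ++r) {
    snp[r] = S.rooms[r].np;
    for (int b = 0; b < 4; ++b) (*snt[b])[r] = S.rooms[r].nt[b];
    sap[r] = S.rooms[r].ap;
    sam[r] = S.rooms[r].am;
  }
  std::vector<int> nn;
  for (int r = 0; r < S.R; ++r) {
    if (S.rooms[r].cell >= 0) continue;
    naked_neighbors(S, r, nn);
    if (nn.empty()) continue;
    Room &rm = S.rooms[r];
    move_counts(S, &rm.np, dnp, r, nn, snp[r], S.P.p_mv);
    if (rna_moves)
      for (int b = 0; b < 4; ++b)
        move_counts(S, &rm.nt[b], *dnt[b], r, nn, (*snt[b])[r], S.P.p_mv);
    if (!naked_stage) {
      move_counts(S, &rm.ap, dap, r, nn, sap[r], S.P.p_mv);
      move_counts(S, &rm.am, dam, r, nn, sam[r], S.P.p_mv);
    }
  }
  for (int r = 0; r < S.R; ++r) {
    S.rooms[r].np += dnp[r];
    for (int b = 0; b < 4; ++b) S.rooms[r].nt[b] += (*dnt[b])[r];
    S.rooms[r].ap += dap[r];
    S.rooms[r].am += dam[r];
  }
  // free strands (mass-dependent rate)
  if (rna_moves) {
    size_t n0 = S.strands.size();
    for (size_t i = 0; i < n0; ++i) {
      Strand &s = S.strands[i];
      if (!s.alive || s.busy_rep || s.rep_bound) continue;
      if (S.rooms[s.room].cell >= 0) continue;
      long m = (long) s.seq.size();
      for (auto &a : s.atts) m += (long) a.seq.size();
      double pm = S.P.p_mv / std::cbrt((double) m);
      naked_neighbors(S, s.room, nn);
      if (nn.empty()) continue;
      if (U() < pm) s.room = nn[pick((int) nn.size())];
    }
  }
  // 8b: protocells
  if (!naked_stage) {
    std::vector<int> order, push_to;
    for (int r = 0; r < S.R; ++r)
      if (S.rooms[r].cell >= 0 && S.cells[S.rooms[r].cell].alive)
        order.push_back(S.rooms[r].cell);
    for (int ci : order) {
      Cell &c = S.cells[ci];
      if (!c.alive) continue;
      if (U() >= S.P.p_mc) continue;
      naked_neighbors(S, c.room, nn);
      if (nn.empty()) continue;
      int target = nn[pick((int) nn.size())];
      int origin = c.room;
      std::vector<int> interior;
      for (size_t i = 0; i < S.strands.size(); ++i)
        if (S.strands[i].alive && S.strands[i].room == origin)
          interior.push_back((int) i);
      S.rooms[origin].cell = -1;  // vacate (origin becomes a push target)
      naked_neighbors(S, target, push_to);
      push_to.erase(std::remove(push_to.begin(), push_to.end(), target),
                    push_to.end());
      Room &T = S.rooms[target];
      // origin is adjacent and naked, so push_to is never empty
      for (long j = 0; j < T.np; ++j) S.rooms[push_to[pick((int) push_to.size())]].np++;
      for (int b = 0; b < 4; ++b)
        for (long j = 0; j < T.nt[b]; ++j)
          S.rooms[push_to[pick((int) push_to.size())]].nt[b]++;
      for (long j = 0; j < T.ap; ++j) S.rooms[push_to[pick((int) push_to.size())]].ap++;
      for (long j = 0; j < T.am; ++j) S.rooms[push_to[pick((int) push_to.size())]].am++;
      T.np = T.ap = T.am = 0;
      for (int b = 0; b < 4; ++b) T.nt[b] = 0;
      for (auto &s : S.strands)
        if (s.alive && s.room == target)
          s.room = push_to[pick((int) push_to.size())];
      S.rooms[target].cell = ci;
      c.room = target;
      for (int id : interior) S.strands[id].room = target;
    }
  }
}

// ---- step driver ------------------------------------------------------------

static void compact_strands(Sim &S) {
  size_t dead = 0;
  for (auto &s : S.strands)
    if (!s.alive) ++dead;
  if (dead * 2 < S.strands.size() || dead < 64) return;
  std::vector<Strand> keep;
  keep.reserve(S.strands.size() - dead);
  std::vector<int> remap(S.strands.size(), -1);
  for (size_t i = 0; i < S.strands.size(); ++i) {
    if (S.strands[i].alive) {
      remap[i] = (int) keep.size();
      keep.push_back(std::move(S.strands[i]));
    }
  }
  for (auto &s : keep) {
    if (s.bound_rep >= 0) s.bound_rep = remap[s.bound_rep];
    if (s.bound_tmpl >= 0) s.bound_tmpl = remap[s.bound_tmpl];
  }
  S.strands = std::move(keep);
}

static void run_phase(Sim &S, int phase) {
  switch (phase) {
    case 1: phase_nt_turnover(S); break;
    case 2: phase_am_turnover(S); break;
    case 3: phase_strand_decay(S); break;
    case 4: phase_random_ligation(S); break;
    case 51: phase_template_state(S); break;
    case 52: phase_rep_bind(S); break;
    case 53: phase_attraction(S); break;
    case 54: phase_template_ligation(S); break;
    case 55: phase_separation(S); break;
    case 6: phase_membranes(S); break;
    case 7: phase_cells(S); break;
    case 8: phase_movement(S); break;
    default: stop("unknown phase");
  }
}

static double prof_t[14];
#ifdef RIBOCELL_PROF
#include <chrono>
#define PROF(i, call) { auto t0=std::chrono::steady_clock::now(); call; prof_t[i]+=std::chrono::duration<double>(std::chrono::steady_clock::now()-t0).count(); }
#else
#define PROF(i, call) call
#endif

static void advance(Sim &S) {
  PROF(0, phase_nt_turnover(S));
  PROF(1, phase_am_turnover(S));
  PROF(2, phase_strand_decay(S));
  PROF(3, phase_random_ligation(S));
  PROF(4, phase_template_state(S));
  PROF(5, phase_rep_bind(S));
  PROF(6, phase_attraction(S));
  PROF(7, phase_template_ligation(S));
  PROF(8, phase_separation(S));
  PROF(9, phase_membranes(S));
  PROF(10, phase_cells(S));
  PROF(11, phase_movement(S));
  S.step++;
  compact_strands(S);
  long long ntu, amu;
  PROF(12, totals(S, ntu, amu));
  if (ntu != S.base_nt || amu != S.base_am)
    stop("conservation violated at step %ld: nt %lld != %lld or am %lld != %lld",
         S.step, ntu, S.base_nt, amu, S.base_am);
}

// [[Rcpp::export]]
NumericVector sim_prof() { return NumericVector(prof_t, prof_t + 14); }

static void init_caches(Sim &S) {
  S.sp_pow[0] = 1.0;
  for (int l = 1; l <= 64; ++l)
    S.sp_pow[l] = std::pow(S.P.p_sp, (double) l);
}

// ---- parameter marshalling --------------------------------------------------

static Params make_params(List pl) {
  Params P;
  P.p_ad = pl["p_ad"]; P.p_adm = pl["p_adm"]; P.p_af = pl["p_af"];
  P.p_afr = pl["p_afr"]; P.p_ajm = pl["p_ajm"]; P.p_alm = pl["p_alm"];
  P.p_app = pl["p_app"]; P.p_at = pl["p_at"]; P.p_bb = pl["p_bb"];
  P.p_cb = pl["p_cb"]; P.p_cd = pl["p_cd"]; P.p_cf = pl["p_cf"];
  P.p_flr = pl["p_flr"]; P.p_fp = pl["p_fp"]; P.p_mc = pl["p_mc"];
  P.p_mf = pl["p_mf"]; P.p_mv = pl["p_mv"]; P.p_nd = pl["p_nd"];
  P.p_nde = pl["p_nde"]; P.p_nf = pl["p_nf"]; P.p_nfr = pl["p_nfr"];
  P.p_npp = pl["p_npp"]; P.p_rb = pl["p_rb"]; P.p_rd = pl["p_rd"];
  P.p_rl = pl["p_rl"]; P.p_rtt = pl["p_rtt"]; P.p_sp = pl["p_sp"];
  P.p_tl = pl["p_tl"]; P.p_tlr = pl["p_tlr"];
  P.N = as<int>(pl["n_grid"]);
  P.t_npb = pl["t_npb"];
  P.t_apb = pl["t_apb"];
  P.l_am = (long) as<double>(pl["l_am"]);
  P.f_op = pl["f_op"]; P.f_si = pl["f_si"]; P.f_bo = pl["f_bo"];
  std::string st = as<std::string>(pl["stage"]);
  P.stage = st == "naked" ? ST_NAKED : (st == "pseudo_protocell" ? ST_PSEUDO : ST_TRUE);
  P.refold = as<bool>(pl["refold"]);
  P.outward_perm = as<bool>(pl["outward_permeation"]);
  P.outside_rna_moves = as<bool>(pl["outside_rna_moves"]);
  {
    std::string am = as<std::string>(pl["attraction"]);
    P.attract_mode = am == "flux" ? 0
                     : (am == "extension" ? 1 : (am == "template" ? 2 : 3));
    std::string sm = as<std::string>(pl["separation"]);
    P.sep_mode = sm == "processive" ? 0 : (sm == "memoryless" ? 1 : 2);
  }
  P.mform = as<std::string>(pl["membrane_form"]) == "constant" ? 1 : 0;
  for (int c = 0; c < 4; ++c) { P.has_ov[c] = false; P.ov_rtt[c] = P.p_rtt; }
  List ov = pl["class_overrides"];
  if (ov.size() > 0) {
    CharacterVector nms = ov.names();
    const char *cls[4] = {"REP", "NSR", "ASR", "CONTROL"};
    for (int i = 0; i < ov.size(); ++i) {
      List o = ov[i];
      for (int c = 0; c < 4; ++c) {
        if (as<std::string>(nms[i]) == cls[c] && o.containsElementNamed("p_rtt")) {
          P.has_ov[c] = true;
          P.ov_rtt[c] = as<double>(o["p_rtt"]);
        }
      }
    }
  }
  return P;
}

static Dom make_dom(int stem_len, List loops) {
  Dom D;
  D.stem = stem_len;
  D.dlen = 2 * stem_len + 4;
  const char *cls[4] = {"REP", "NSR", "ASR", "CONTROL"};
  for (int c = 0; c < 4; ++c) {
    IntegerVector lv = loops[cls[c]];
    D.loops[c] = std::vector<int>(lv.begin(), lv.end());
  }
  return D;
}

// ---- exported interface -----------------------------------------------------

// [[Rcpp::export]]
SEXP sim_new(List params, int stem_len, List loops) {
  Sim *S = new Sim();
  S->P = make_params(params);
  S->D = make_dom(stem_len, loops);
  S->N = S->P.N;
  S->R = S->N * S->N;
  S->rooms.assign(S->R, Room());
  init_caches(*S);
  XPtr<Sim> xp(S, true);
  return xp;
}

// [[Rcpp::export]]
void sim_set_param(SEXP xp, List params) {
  XPtr<Sim> S(xp);
  if (as<int>(params["n_grid"]) != S->N) stop("cannot change grid size");
  S->P = make_params(params);
  init_caches(*S);
}

// distribute the initial precursor totals uniformly at random over rooms
// (draw discipline: each molecule picks a room with one uniform draw)
// [[Rcpp::export]]
void sim_initialize(SEXP xp) {
  XPtr<Sim> S(xp);
  long tn = (long) S->P.t_npb, ta = (long) S->P.t_apb;
  for (long j = 0; j < tn; ++j) S->rooms[pick(S->R)].np++;
  for (long j = 0; j < ta; ++j) S->rooms[pick(S->R)].ap++;
  rebaseline(*S);
}

// [[Rcpp::export]]
void sim_advance(SEXP xp, int nsteps) {
  XPtr<Sim> S(xp);
  for (int i = 0; i < nsteps; ++i) advance(*S);
}

// [[Rcpp::export]]
void sim_phase(SEXP xp, int phase) {
  XPtr<Sim> S(xp);
  run_phase(*S, phase);
}

// [[Rcpp::export]]
List sim_info(SEXP xp) {
  XPtr<Sim> S(xp);
  return List::create(_["n_grid"] = S->N, _["step"] = (double) S->step,
                      _["n_strands"] = (int) S->strands.size(),
                      _["base_nt"] = (double) S->base_nt,
                      _["base_am"] = (double) S->base_am);
}

// ---- state construction / mutation (tests, inoculation) ---------------------

// [[Rcpp::export]]
void sim_set_pool(SEXP xp, int room, long np, IntegerVector nt, long ap, long am) {
  XPtr<Sim> S(xp);
  Pool p = pool_at(*S, room);
  *p.np = np;
  for (int b = 0; b < 4; ++b) p.nt[b] = nt[b];
  *p.ap = ap;
  *p.am = am;
  rebaseline(*S);
}

// [[Rcpp::export]]
int sim_add_strand(SEXP xp, int room, IntegerVector seq, bool folded) {
  XPtr<Sim> S(xp);
  Strand s;
  s.room = room;
  s.folded = folded;
  S->strands.push_back(s);
  set_seq(*S, S->strands.back(), std::vector<uint8_t>(seq.begin(), seq.end()));
  rebaseline(*S);
  return (int) S->strands.size() - 1;
}

// [[Rcpp::export]]
void sim_add_attachment(SEXP xp, int sid, int start, IntegerVector seq,
                        IntegerVector ok, IntegerVector paired,
                        bool ligated = false) {
  XPtr<Sim> S(xp);
  Strand &s = S->strands[sid];
  s.folded = false;
  Att a;
  a.start = start;
  a.ligated = ligated;
  a.seq = std::vector<uint8_t>(seq.begin(), seq.end());
  a.ok = std::vector<uint8_t>(ok.begin(), ok.end());
  a.paired = std::vector<uint8_t>(paired.begin(), paired.end());
  auto it = s.atts.begin();
  while (it != s.atts.end() && it->start < start) ++it;
  s.atts.insert(it, a);
  rebaseline(*S);
}

// [[Rcpp::export]]
void sim_set_template(SEXP xp, int sid, bool tmpl) {
  XPtr<Sim> S(xp);
  S->strands[sid].folded = !tmpl;
}

// [[Rcpp::export]]
void sim_bind_rep(SEXP xp, int tid, int rid) {
  XPtr<Sim> S(xp);
  S->strands[tid].folded = false;
  S->strands[tid].rep_bound = true;
  S->strands[tid].bound_rep = rid;
  S->strands[rid].busy_rep = true;
  S->strands[rid].bound_tmpl = tid;
}

// [[Rcpp::export]]
void sim_make_cell(SEXP xp, int room, long b, bool encompass) {
  XPtr<Sim> S(xp);
  if (S->rooms[room].cell >= 0) stop("room already protocell-occupied");
  Cell c;
  c.room = room;
  c.b = b;
  if (encompass) {
    Room &rm = S->rooms[room];
    c.np = rm.np;
    for (int bb = 0; bb < 4; ++bb) c.nt[bb] = rm.nt[bb];
    c.ap = rm.ap;
    c.am = rm.am;
    rm.np = rm.ap = rm.am = 0;
    for (int bb = 0; bb < 4; ++bb) rm.nt[bb] = 0;
  }
  S->cells.push_back(c);
  S->rooms[room].cell = (int) S->cells.size() - 1;
  rebaseline(*S);
}

// [[Rcpp::export]]
void sim_corrupt_pool(SEXP xp, int room, long dnp) {
  // deliberately breaks conservation (audit tests); baseline untouched
  XPtr<Sim> S(xp);
  Pool p = pool_at(*S, room);
  *p.np += dnp;
}

// ---- accessors --------------------------------------------------------------

// [[Rcpp::export]]
List sim_audit(SEXP xp) {
  XPtr<Sim> S(xp);
  long long ntu, amu;
  totals(*S, ntu, amu);
  return List::create(
      _["nt_units"] = (double) ntu, _["am_units"] = (double) amu,
      _["nt_expected"] = (double) S->base_nt,
      _["am_expected"] = (double) S->base_am,
      _["ok"] = (ntu == S->base_nt && amu == S->base_am));
}

// [[Rcpp::export]]
List sim_dump(SEXP xp) {
  XPtr<Sim> S(xp);
  int R = S->R;
  IntegerVector np(R), ap(R), am(R), cell(R);
  IntegerMatrix nt(R, 4);
  for (int r = 0; r < R; ++r) {
    np[r] = (int) S->rooms[r].np;
    for (int b = 0; b < 4; ++b) nt(r, b) = (int) S->rooms[r].nt[b];
    ap[r] = (int) S->rooms[r].ap;
    am[r] = (int) S->rooms[r].am;
    cell[r] = S->rooms[r].cell;
  }
  List cells(S->cells.size());
  for (size_t i = 0; i < S->cells.size(); ++i) {
    Cell &c = S->cells[i];
    cells[i] = List::create(
        _["alive"] = c.alive, _["room"] = c.room, _["b"] = (double) c.b,
        _["np"] = (double) c.np,
        _["nt"] = IntegerVector::create((int) c.nt[0], (int) c.nt[1],
                                        (int) c.nt[2], (int) c.nt[3]),
        _["ap"] = (double) c.ap, _["am"] = (double) c.am);
  }
  List strands(S->strands.size());
  for (size_t i = 0; i < S->strands.size(); ++i) {
    Strand &s = S->strands[i];
    List atts(s.atts.size());
    for (size_t j = 0; j < s.atts.size(); ++j) {
      Att &a = s.atts[j];
      atts[j] = List::create(
          _["start"] = a.start, _["ligated"] = (bool) a.ligated,
          _["seq"] = IntegerVector(a.seq.begin(), a.seq.end()),
          _["ok"] = IntegerVector(a.ok.begin(), a.ok.end()),
          _["paired"] = IntegerVector(a.paired.begin(), a.paired.end()));
    }
    strands[i] = List::create(
        _["alive"] = s.alive, _["room"] = s.room, _["folded"] = s.folded,
        _["rep_bound"] = s.rep_bound, _["bound_rep"] = s.bound_rep,
        _["busy_rep"] = s.busy_rep,
        _["seq"] = IntegerVector(s.seq.begin(), s.seq.end()),
        _["cls"] = s.cls, _["atts"] = atts);
  }
  return List::create(_["step"] = (double) S->step, _["np"] = np, _["nt"] = nt,
                      _["ap"] = ap, _["am"] = am, _["cell"] = cell,
                      _["cells"] = cells, _["strands"] = strands);
}

// per-class strand counts and protocell composition classes
// [[Rcpp::export]]
List sim_census_cpp(SEXP xp) {
  XPtr<Sim> S(xp);
  long rep = 0, nsr = 0, asr = 0, ctrl = 0, other = 0;
  for (auto &s : S->strands) {
    if (!s.alive) continue;
    if (s.cls == 0) { other++; continue; }
    if (s.cls & CL_REP) rep++;
    if (s.cls & CL_NSR) nsr++;
    if (s.cls & CL_ASR) asr++;
    if (s.cls & CL_CONTROL) ctrl++;
  }
  long long np = 0, ntt = 0, ap = 0, amf = 0, memb = 0;
  for (int r = 0; r < S->R; ++r) {
    np += S->rooms[r].np;
    for (int b = 0; b < 4; ++b) ntt += S->rooms[r].nt[b];
    ap += S->rooms[r].ap;
    amf += S->rooms[r].am;
  }
  long cells_total = 0;
  long comp[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  // order: all3, rep_nsr, rep_asr, nsr_asr, rep_only, nsr_only, asr_only, none
  for (auto &c : S->cells) {
    if (!c.alive) continue;
    cells_total++;
    np += c.np;
    for (int b = 0; b < 4; ++b) ntt += c.nt[b];
    ap += c.ap;
    amf += c.am;
    memb += c.b;
    int has = 0;
    for (auto &s : S->strands)
      if (s.alive && s.room == c.room) has |= s.cls;
    bool hr = has & CL_REP, hn = has & CL_NSR, ha = has & CL_ASR;
    if (hr && hn && ha) comp[0]++;
    else if (hr && hn) comp[1]++;
    else if (hr && ha) comp[2]++;
    else if (hn && ha) comp[3]++;
    else if (hr) comp[4]++;
    else if (hn) comp[5]++;
    else if (ha) comp[6]++;
    else comp[7]++;
  }
  return List::create(
      _["rep"] = (double) rep, _["nsr"] = (double) nsr, _["asr"] = (double) asr,
      _["control"] = (double) ctrl, _["other_rna"] = (double) other,
      _["np"] = (double) np, _["nt"] = (double) ntt, _["ap"] = (double) ap,
      _["am_free"] = (double) amf, _["am_membrane"] = (double) memb,
      _["cells_total"] = (double) cells_total,
      _["cells_all3"] = (double) comp[0], _["cells_rep_nsr"] = (double) comp[1],
      _["cells_rep_asr"] = (double) comp[2], _["cells_nsr_asr"] = (double) comp[3],
      _["cells_rep_only"] = (double) comp[4], _["cells_nsr_only"] = (double) comp[5],
      _["cells_asr_only"] = (double) comp[6], _["cells_none"] = (double) comp[7]);
}

// per-room snapshot (spatial layout)
// [[Rcpp::export]]
List sim_snapshot_cpp(SEXP xp) {
  XPtr<Sim> S(xp);
  int R = S->R, N = S->N;
  IntegerVector x(R), y(R), occ(R), b(R), np(R), ntv(R), ap(R), am(R),
      rep(R), nsr(R), asr(R), ctrl(R), other(R);
  for (int r = 0; r < R; ++r) {
    x[r] = r % N;
    y[r] = r / N;
    int ci = S->rooms[r].cell;
    occ[r] = ci >= 0 ? 1 : 0;
    Pool p = pool_at(*S, r);
    b[r] = ci >= 0 ? (int) S->cells[ci].b : 0;
    np[r] = (int) *p.np;
    ntv[r] = (int) (p.nt[0] + p.nt[1] + p.nt[2] + p.nt[3]);
    ap[r] = (int) *p.ap;
    am[r] = (int) *p.am;
    rep[r] = nsr[r] = asr[r] = ctrl[r] = other[r] = 0;
  }
  for (auto &s : S->strands) {
    if (!s.alive) continue;
    if (s.cls == 0) other[s.room]++;
    if (s.cls & CL_REP) rep[s.room]++;
    if (s.cls & CL_NSR) nsr[s.room]++;
    if (s.cls & CL_ASR) asr[s.room]++;
    if (s.cls & CL_CONTROL) ctrl[s.room]++;
  }
  return List::create(_["x"] = x, _["y"] = y, _["protocell"] = occ,
                      _["membrane"] = b, _["np"] = np, _["nt"] = ntv,
                      _["ap"] = ap, _["am"] = am, _["rep"] = rep,
                      _["nsr"] = nsr, _["asr"] = asr, _["control"] = ctrl,
                      _["other_rna"] = other);
}

// all living strand sequences with location metadata (FASTA export)
// [[Rcpp::export]]
List sim_strand_table(SEXP xp) {
  XPtr<Sim> S(xp);
  std::vector<int> room, cls, inside;
  std::vector<std::string> seqs;
  const char *B = "AUCG";
  for (auto &s : S->strands) {
    if (!s.alive) continue;
    std::string q;
    for (auto b : s.seq) q.push_back(B[b]);
    seqs.push_back(q);
    room.push_back(s.room);
    cls.push_back(s.cls);
    inside.push_back(S->rooms[s.room].cell >= 0 ? 1 : 0);
  }
  return List::create(_["room"] = wrap(room), _["cls"] = wrap(cls),
                      _["inside"] = wrap(inside), _["seq"] = wrap(seqs));
}

// [[Rcpp::export]]
int classify_seq_cpp(IntegerVector seq, int stem_len, List loops) {
  Dom D = make_dom(stem_len, loops);
  return classify(std::vector<uint8_t>(seq.begin(), seq.end()), D);
}
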