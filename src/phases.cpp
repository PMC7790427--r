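#include <Rcpp.h>
using namespace Rcpp;

// Per-agent phase kernels for the simulation engine. Each phase receives the
// agent tables as lists of parallel vectors plus the occupancy matrices,
// clones what it mutates, and returns the updated pieces. All random draws
// use R's RNG stream (unif_rand), so set.seed() at the R level fully
// determines every trajectory.
//
// Occupancy coding: occ_kind 0 = empty, 1 = cancer cell, 2 = macrophage,
// 3 = T cell; occ_id is the 1-based row index into the matching agent table.

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Forward pass of the 3-input / 4-hidden-sigmoid / 1-output surrogate.
// Inputs are min-max normalized and clamped to the training ranges.
// Returns the M1 probability (output unit activation).
static double nn_forward(double il4, double ifng, double pi3k,
                         const NumericMatrix &W1, const NumericVector &b1,
                         const NumericVector &w2, double b2,
                         const NumericVector &lo, const NumericVector &hi) {
  double x[3] = {il4, ifng, pi3k};
  double xn[3];
  for (int k = 0; k < 3; ++k) {
    double range = hi[k] - lo[k];
    double v = (range > 0) ? (x[k] - lo[k]) / range : 0.0;
    if (v < 0) v = 0;
    if (v > 1) v = 1;
    xn[k] = v;
  }
  double out = b2;
  for (int j = 0; j < 4; ++j) {
    double z = b1[j];
    for (int k = 0; k < 3; ++k) z += W1(j, k) * xn[k];
    out += w2[j] * sigmoid(z);
  }
  return sigmoid(out);
}

// Exposed for cross-checking the engine's surrogate arithmetic against the
// R-level predict path.
// [[Rcpp::export]]
NumericVector cpp_nn_forward(NumericVector il4, NumericVector ifng,
                             NumericVector pi3k, List nn) {
  NumericMatrix W1 = nn["W1"];
  NumericVector b1 = nn["b1"], w2 = nn["w2"], lo = nn["in_lo"], hi = nn["in_hi"];
  double b2 = as<double>(nn["b2"]);
  int n = il4.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = nn_forward(il4[i], ifng[i], pi3k[i], W1, b1, w2, b2, lo, hi);
  return out;
}

// Uniform integer in [0, n-1] from R's RNG.
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Pick a migration target by steepest ascent on `field` over the empty
// in-bounds neighbors; ties broken uniformly at random (a flat field yields
// an unbiased random walk). Chemotactic sensing has a floor and a ceiling:
// values below `floor_` are indistinguishable from zero (cells outside the
// sensing radius random-walk instead of homing onto vanishing field tails),
// and values above `sat` compare equal (receptor saturation, so cells deep
// in a saturated zone churn in an undirected local walk). Cells also remain
// motile: an agent blocked on its uphill side steps to the best reachable
// site instead of freezing. Together these keep immune crowds near the
// tumor loose instead of congealing into a growth-blocking shell. Returns
// true if the agent moves (false only when fully blocked), with the target
// written to (tr, tc).
static bool pick_ascent_move(int r, int c, const NumericMatrix &field,
                             double floor_, double sat,
                             const IntegerMatrix &occ_kind,
                             const IntegerMatrix &off,
                             int &tr, int &tc) {
  const int nr = field.nrow(), nc_ = field.ncol();
  int cand_r[8], cand_c[8];
  int ncand = 0;
  double best = 0.0;
  for (int m = 0; m < off.nrow(); ++m) {
    int rr = r + off(m, 0), cc = c + off(m, 1);
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc_) continue;
    if (occ_kind(rr, cc) != 0) continue;
    double v = field(rr, cc);
    if (v < floor_) v = 0.0;
    if (v > sat) v = sat;
    if (ncand == 0 || v > best) {
      best = v; ncand = 1; cand_r[0] = rr; cand_c[0] = cc;
    } else if (v == best) {
      cand_r[ncand] = rr; cand_c[ncand] = cc; ++ncand;
    }
  }
  if (ncand == 0) { tr = r; tc = c; return false; }  // blocked: stay
  int pick = (ncand == 1) ? 0 : runif_int(ncand);
  tr = cand_r[pick]; tc = cand_c[pick];
  return true;
}

// Collect empty in-bounds neighbors; returns count, sites in (er, ec).
static int empty_neighbors(int r, int c, const IntegerMatrix &occ_kind,
                           const IntegerMatrix &off, int *er, int *ec) {
  const int nr = occ_kind.nrow(), nc_ = occ_kind.ncol();
  int n = 0;
  for (int m = 0; m < off.nrow(); ++m) {
    int rr = r + off(m, 0), cc = c + off(m, 1);
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc_) continue;
    if (occ_kind(rr, cc) == 0) { er[n] = rr; ec[n] = cc; ++n; }
  }
  return n;
}

// ---------------------------------------------------------------------------
// Macrophage phase: aging/death, differentiation via the surrogate when the
// local activation factor licenses it and the 24-h redifferentiation clock
// has elapsed, then chemotactic migration up the activation-factor field.
// [[Rcpp::export]]
List cpp_macrophage_phase(IntegerVector order, List mac,
                          IntegerMatrix occ_kind_in, IntegerMatrix occ_id_in,
                          NumericMatrix act, NumericMatrix il4,
                          NumericMatrix ifng, List nn, List pars) {
  IntegerVector row = clone(as<IntegerVector>(mac["row"]));
  IntegerVector col = clone(as<IntegerVector>(mac["col"]));
  IntegerVector phen = clone(as<IntegerVector>(mac["phen"]));
  NumericVector age = clone(as<NumericVector>(mac["age"]));
  NumericVector clock = clone(as<NumericVector>(mac["clock"]));
  LogicalVector alive = clone(as<LogicalVector>(mac["alive"]));
  IntegerMatrix occ_kind = clone(occ_kind_in);
  IntegerMatrix occ_id = clone(occ_id_in);

  const double dt = as<double>(pars["dt_h"]);
  const double lifespan = as<double>(pars["mac_lifespan_h"]);
  const double thresh = as<double>(pars["act_threshold"]);
  const double rediff = as<double>(pars["rediff_period_h"]);
  const double pi3k = as<double>(pars["pi3k_activity"]);
  const double chemo_floor = as<double>(pars["chemo_floor"]);
  const double sat = as<double>(pars["act_sat"]);
  const IntegerMatrix off = as<IntegerMatrix>(pars["offsets"]);

  NumericMatrix W1 = nn["W1"];
  NumericVector b1 = nn["b1"], w2 = nn["w2"], lo = nn["in_lo"], hi = nn["in_hi"];
  const double b2 = as<double>(nn["b2"]);

  RNGScope rng;
  for (int oi = 0; oi < order.size(); ++oi) {
    int i = order[oi] - 1;
    if (!alive[i]) continue;
    age[i] += dt;
    int r = row[i] - 1, c = col[i] - 1;
    if (age[i] >= lifespan) {
      alive[i] = false;
      occ_kind(r, c) = 0; occ_id(r, c) = 0;
      continue;
    }
    clock[i] += dt;
    if (clock[i] >= rediff && act(r, c) >= thresh) {
      clock[i] = 0.0;
      double p = nn_forward(il4(r, c), ifng(r, c), pi3k, W1, b1, w2, b2, lo, hi);
      phen[i] = (p > 0.5) ? 1 : 2;   // 1 = M1, 2 = M2
    }
    int tr, tc;
    if (pick_ascent_move(r, c, act, chemo_floor, sat, occ_kind, off, tr, tc)) {
      occ_kind(r, c) = 0; occ_id(r, c) = 0;
      occ_kind(tr, tc) = 2; occ_id(tr, tc) = i + 1;
      row[i] = tr + 1; col[i] = tc + 1;
    }
  }

  return List::create(
    _["mac"] = List::create(_["row"] = row, _["col"] = col, _["phen"] = phen,
                            _["age"] = age, _["clock"] = clock,
                            _["alive"] = alive),
    _["occ_kind"] = occ_kind, _["occ_id"] = occ_id);
}

// ---------------------------------------------------------------------------
// T-cell phase. First resolves ongoing engagements (timers advance; expiry
// kills the cancer cell, spends one unit of the T cell's kill budget and
// frees or exhausts it). Then each unengaged T cell, in random order: ages,
// may attempt activation (needs adjacent antigen: cancer cell or M1
// macrophage; probability from the macrophage-weighted sigmoid), and if
// active may proliferate into an empty neighbor and initiate killing of an
// adjacent unengaged cancer cell. Cells that did not just engage migrate up
// the activation-factor field.
// [[Rcpp::export]]
List cpp_tcell_phase(IntegerVector order, List tc, List ca,
                     IntegerMatrix occ_kind_in, IntegerMatrix occ_id_in,
                     NumericMatrix act, List pars) {
  IntegerVector row = clone(as<IntegerVector>(tc["row"]));
  IntegerVector col = clone(as<IntegerVector>(tc["col"]));
  IntegerVector state = clone(as<IntegerVector>(tc["state"])); // 0 recruited, 1 active, 2 exhausted
  IntegerVector kills = clone(as<IntegerVector>(tc["kills"]));
  IntegerVector engaged = clone(as<IntegerVector>(tc["engaged"]));
  NumericVector timer = clone(as<NumericVector>(tc["timer"]));
  NumericVector age = clone(as<NumericVector>(tc["age"]));
  LogicalVector alive = clone(as<LogicalVector>(tc["alive"]));

  IntegerVector ca_row = as<IntegerVector>(ca["row"]);
  IntegerVector ca_col = as<IntegerVector>(ca["col"]);
  IntegerVector ca_engaged = clone(as<IntegerVector>(ca["engaged"]));
  LogicalVector ca_alive = clone(as<LogicalVector>(ca["alive"]));

  IntegerMatrix occ_kind = clone(occ_kind_in);
  IntegerMatrix occ_id = clone(occ_id_in);

  IntegerVector mac_phen = as<IntegerVector>(pars["mac_phen"]);

  const double dt = as<double>(pars["dt_h"]);
  const double lifespan = as<double>(pars["tc_lifespan_h"]);
  const double k_act = as<double>(pars["act_k"]);
  const double s_act = as<double>(pars["act_s"]);
  const double engage_h = as<double>(pars["engage_duration_h"]);
  const int max_kills = as<int>(pars["tc_max_kills"]);
  const double p_div = as<double>(pars["tc_p_divide"]);
  const bool activation_on = as<bool>(pars["activation_enabled"]);
  const double chemo_floor = as<double>(pars["chemo_floor"]);
  const double sat = as<double>(pars["act_sat"]);
  const IntegerMatrix off = as<IntegerMatrix>(pars["offsets"]);
  const int nr = occ_kind.nrow(), ncl = occ_kind.ncol();

  int n_kills = 0;

  // Daughter cells born this phase (appended by the R caller).
  std::vector<int> new_row, new_col;

  RNGScope rng;

  // -- engagement resolution --------------------------------------------
  for (int i = 0; i < row.size(); ++i) {
    if (!alive[i] || engaged[i] == 0) continue;
    timer[i] -= dt;
    if (timer[i] <= 1e-9) {
      int j = engaged[i] - 1;
      if (j >= 0 && j < ca_alive.size() && ca_alive[j]) {
        ca_alive[j] = false;
        ca_engaged[j] = 0;
        occ_kind(ca_row[j] - 1, ca_col[j] - 1) = 0;
        occ_id(ca_row[j] - 1, ca_col[j] - 1) = 0;
        ++n_kills;
      }
      engaged[i] = 0;
      timer[i] = 0.0;
      kills[i] -= 1;
      if (kills[i] <= 0) state[i] = 2;
    }
  }

  // -- free T cells act in random order ----------------------------------
  for (int oi = 0; oi < order.size(); ++oi) {
    int i = order[oi] - 1;
    if (!alive[i] || engaged[i] > 0) continue;
    age[i] += dt;
    int r = row[i] - 1, c = col[i] - 1;
    if (age[i] >= lifespan) {
      alive[i] = false;
      occ_kind(r, c) = 0; occ_id(r, c) = 0;
      continue;
    }

    // neighbor census: antigen presence and M1/M2 counts
    int nM1 = 0, nM2 = 0;
    bool antigen = false;
    for (int m = 0; m < off.nrow(); ++m) {
      int rr = r + off(m, 0), cc = c + off(m, 1);
      if (rr < 0 || rr >= nr || cc < 0 || cc >= ncl) continue;
      int kind = occ_kind(rr, cc);
      if (kind == 1) antigen = true;
      else if (kind == 2) {
        int ph = mac_phen[occ_id(rr, cc) - 1];
        if (ph == 1) { ++nM1; antigen = true; }
        else if (ph == 2) ++nM2;
      }
    }

    if (state[i] == 0 && activation_on && antigen) {
      double arg = (1.0 - (double)nM2 / (nM1 + 1.0)) - s_act;
      double p = 1.0 / (1.0 + std::exp(-k_act * arg));
      if (unif_rand() < p) state[i] = 1;
    }

    bool just_engaged = false;
    if (state[i] == 1) {
      // proliferation into an empty neighbor
      if (p_div > 0 && unif_rand() < p_div) {
        int er[8], ec[8];
        int ne = empty_neighbors(r, c, occ_kind, off, er, ec);
        if (ne > 0) {
          int pick = runif_int(ne);
          int id = row.size() + (int)new_row.size() + 1;
          new_row.push_back(er[pick] + 1);
          new_col.push_back(ec[pick] + 1);
          occ_kind(er[pick], ec[pick]) = 3;
          occ_id(er[pick], ec[pick]) = id;
        }
      }
      // initiate killing of an adjacent unengaged cancer cell
      if (kills[i] > 0) {
        int tr_[8], tj_[8];
        int nt = 0;
        for (int m = 0; m < off.nrow(); ++m) {
          int rr = r + off(m, 0), cc = c + off(m, 1);
          if (rr < 0 || rr >= nr || cc < 0 || cc >= ncl) continue;
          if (occ_kind(rr, cc) != 1) continue;
          int j = occ_id(rr, cc) - 1;
          if (ca_alive[j] && ca_engaged[j] == 0) { tr_[nt] = rr; tj_[nt] = j; ++nt; }
        }
        if (nt > 0) {
          int pick = runif_int(nt);
          int j = tj_[pick];
          engaged[i] = j + 1;
          ca_engaged[j] = i + 1;
          timer[i] = engage_h;
          just_engaged = true;
        }
      }
    }

    if (!just_engaged) {
      int tr, tcn;
      if (pick_ascent_move(r, c, act, chemo_floor, sat, occ_kind, off, tr, tcn)) {
        occ_kind(r, c) = 0; occ_id(r, c) = 0;
        occ_kind(tr, tcn) = 3; occ_id(tr, tcn) = i + 1;
        row[i] = tr + 1; col[i] = tcn + 1;
      }
    }
  }

  // append daughters (naive state, full kill budget)
  int n_new = (int)new_row.size();
  if (n_new > 0) {
    std::vector<int> vrow = as<std::vector<int> >(row), vcol = as<std::vector<int> >(col),
      vstate = as<std::vector<int> >(state), vkills = as<std::vector<int> >(kills),
      veng = as<std::vector<int> >(engaged);
    std::vector<double> vtimer = as<std::vector<double> >(timer), vage = as<std::vector<double> >(age);
    std::vector<int> valive(alive.begin(), alive.end());
    for (int q = 0; q < n_new; ++q) {
      vrow.push_back(new_row[q]); vcol.push_back(new_col[q]);
      vstate.push_back(0); vkills.push_back(max_kills);
      veng.push_back(0); vtimer.push_back(0.0); vage.push_back(0.0);
      valive.push_back(1);
    }
    row = wrap(vrow); col = wrap(vcol); state = wrap(vstate); kills = wrap(vkills);
    engaged = wrap(veng); timer = wrap(vtimer); age = wrap(vage);
    alive = LogicalVector(valive.begin(), valive.end());
  }

  return List::create(
    _["tc"] = List::create(_["row"] = row, _["col"] = col, _["state"] = state,
                           _["kills"] = kills, _["engaged"] = engaged,
                           _["timer"] = timer, _["age"] = age,
                           _["alive"] = alive),
    _["ca_engaged"] = ca_engaged, _["ca_alive"] = ca_alive,
    _["occ_kind"] = occ_kind, _["occ_id"] = occ_id,
    _["n_kills"] = n_kills, _["n_births"] = n_new);
}

// ---------------------------------------------------------------------------
// Cancer-cell phase: the proliferation clock advances unless the cell is
// quiescent or engaged; at the division period the cell divides into a
// uniformly random empty neighbor or becomes quiescent when surrounded
// (re-checking for space every subsequent step). Lifespan is either a
// maximum number of divisions (default) or an age in hours.
// [[Rcpp::export]]
List cpp_cancer_phase(IntegerVector order, List ca,
                      IntegerMatrix occ_kind_in, IntegerMatrix occ_id_in,
                      List pars) {
  IntegerVector row = clone(as<IntegerVector>(ca["row"]));
  IntegerVector col = clone(as<IntegerVector>(ca["col"]));
  NumericVector clock = clone(as<NumericVector>(ca["clock"]));
  IntegerVector divisions = clone(as<IntegerVector>(ca["divisions"]));
  LogicalVector quiescent = clone(as<LogicalVector>(ca["quiescent"]));
  IntegerVector engaged = clone(as<IntegerVector>(ca["engaged"]));
  NumericVector age = clone(as<NumericVector>(ca["age"]));
  LogicalVector alive = clone(as<LogicalVector>(ca["alive"]));
  IntegerMatrix occ_kind = clone(occ_kind_in);
  IntegerMatrix occ_id = clone(occ_id_in);

  const double dt = as<double>(pars["dt_h"]);
  const double period = as<double>(pars["ca_period_h"]);
  const std::string mode = as<std::string>(pars["ca_lifespan_mode"]);
  const int max_div = as<int>(pars["ca_max_divisions"]);
  const double lifespan_h = as<double>(pars["ca_lifespan_h"]);
  const IntegerMatrix off = as<IntegerMatrix>(pars["offsets"]);
  const bool by_hours = (mode == "hours");

  int n_deaths = 0, n_births = 0;
  std::vector<int> new_row, new_col;

  RNGScope rng;
  for (int oi = 0; oi < order.size(); ++oi) {
    int i = order[oi] - 1;
    if (!alive[i] || engaged[i] > 0) continue;
    age[i] += dt;
    int r = row[i] - 1, c = col[i] - 1;
    if (by_hours && age[i] >= lifespan_h) {
      alive[i] = false;
      occ_kind(r, c) = 0; occ_id(r, c) = 0;
      ++n_deaths;
      continue;
    }
    if (!quiescent[i]) clock[i] += dt;
    if (clock[i] >= period) {
      int er[8], ec[8];
      int ne = empty_neighbors(r, c, occ_kind, off, er, ec);
      if (ne > 0) {
        int pick = runif_int(ne);
        int id = row.size() + (int)new_row.size() + 1;
        new_row.push_back(er[pick] + 1);
        new_col.push_back(ec[pick] + 1);
        occ_kind(er[pick], ec[pick]) = 1;
        occ_id(er[pick], ec[pick]) = id;
        ++n_births;
        clock[i] = 0.0;
        quiescent[i] = false;
        divisions[i] += 1;
        if (!by_hours && divisions[i] >= max_div) {
          alive[i] = false;
          occ_kind(r, c) = 0; occ_id(r, c) = 0;
          ++n_deaths;
        }
      } else {
        quiescent[i] = true;
      }
    }
  }

  int n_new = (int)new_row.size();
  if (n_new > 0) {
    std::vector<int> vrow = as<std::vector<int> >(row), vcol = as<std::vector<int> >(col),
      vdiv = as<std::vector<int> >(divisions), veng = as<std::vector<int> >(engaged);
    std::vector<double> vclock = as<std::vector<double> >(clock), vage = as<std::vector<double> >(age);
    std::vector<int> vqui(quiescent.begin(), quiescent.end()), valive(alive.begin(), alive.end());
    for (int q = 0; q < n_new; ++q) {
      vrow.push_back(new_row[q]); vcol.push_back(new_col[q]);
      vclock.push_back(0.0); vdiv.push_back(0); vqui.push_back(0);
      veng.push_back(0); vage.push_back(0.0); valive.push_back(1);
    }
    row = wrap(vrow); col = wrap(vcol); clock = wrap(vclock); divisions = wrap(vdiv);
    engaged = wrap(veng); age = wrap(vage);
    quiescent = LogicalVector(vqui.begin(), vqui.end());
    alive = LogicalVector(valive.begin(), valive.end());
  }

  return List::create(
    _["ca"] = List::create(_["row"] = row, _["col"] = col, _["clock"] = clock,
                           _["divisions"] = divisions, _["quiescent"] = quiescent,
                           _["engaged"] = engaged, _["age"] = age,
                           _["alive"] = alive),
    _["occ_kind"] = occ_kind, _["occ_id"] = occ_id,
    _["n_deaths"] = n_deaths, _["n_births"] = n_births);
}
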