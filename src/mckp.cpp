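// Exact solver for the per-(condition, scenario) assignment problem:
// a multiple-choice knapsack. Minimize total cost subject to one plan per
// patient and sum of selected readmission means <= cap. Branch-and-bound
// with an LP-relaxation bound built from per-patient convex hulls; DFS
// explores plan indices in ascending order and only strict cost
// improvements replace the incumbent, so among equal-cost optima the
// lexicographically smallest plan-index vector is returned.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Plan { double cost, mu; int idx; };       // idx is 0-based plan index
struct Seg  { double slope, dmu, dcost; int patient; };

const double CAP_TOL = 1e-9;      // absolute tolerance on the mu constraint

struct Instance {
  int P;
  std::vector<std::vector<Plan>> kept;   // index-aware non-dominated, by (cost, idx)
  std::vector<std::vector<Plan>> hull;   // convex hull, mu decreasing / cost increasing
  std::vector<Seg> segs;                 // all hull segments, slope ascending
  // suffix sums over patients d..P-1
  std::vector<double> suf_base_cost, suf_base_mu, suf_min_mu;
  std::vector<double> suf_lex_cost, suf_lex_mu;
  std::vector<int> lex_plan;             // lowest-index min-cost plan per patient
  double cap;
};

// Dominance keeping the tie-break contract: drop plan j' when some other
// plan j has cost <= and mu <=, and is either strictly cheaper or has a
// lower index. (Equal-cost lower-mu plans with a *higher* index are kept:
// the lower-index plan may still be the lexicographic choice.)
std::vector<Plan> keep_nondominated(const std::vector<Plan>& all) {
  std::vector<Plan> out;
  for (size_t i = 0; i < all.size(); ++i) {
    bool dom = false;
    for (size_t j = 0; j < all.size() && !dom; ++j) {
      if (i == j) continue;
      const Plan &a = all[j], &b = all[i];
      if (a.cost <= b.cost && a.mu <= b.mu &&
          (a.cost < b.cost || a.idx < b.idx)) dom = true;
    }
    if (!dom) out.push_back(all[i]);
  }
  std::sort(out.begin(), out.end(), [](const Plan& a, const Plan& b) {
    if (a.cost != b.cost) return a.cost < b.cost;
    return a.idx < b.idx;
  });
  return out;
}

// Pareto frontier (strict dominance) then lower convex hull in (mu, cost),
// ordered by mu decreasing / cost increasing, slopes strictly increasing.
std::vector<Plan> convex_hull(const std::vector<Plan>& all) {
  std::vector<Plan> fr;
  for (size_t i = 0; i < all.size(); ++i) {
    bool dom = false;
    for (size_t j = 0; j < all.size() && !dom; ++j) {
      if (i == j) continue;
      const Plan &a = all[j], &b = all[i];
      if (a.cost <= b.cost && a.mu <= b.mu &&
          (a.cost < b.cost || a.mu < b.mu ||
           (a.cost == b.cost && a.mu == b.mu && a.idx < b.idx))) dom = true;
    }
    if (!dom) fr.push_back(all[i]);
  }
  std::sort(fr.begin(), fr.end(), [](const Plan& a, const Plan& b) {
    return a.mu > b.mu;   // frontier: mu strictly decreasing, cost increasing
  });
  std::vector<Plan> h;
  for (const Plan& p : fr) {
    while (h.size() >= 2) {
      const Plan &a = h[h.size() - 2], &b = h[h.size() - 1];
      // slope a->b vs a->p (cost increase per unit mu reduction)
      double s1 = (b.cost - a.cost) * (a.mu - p.mu);
      double s2 = (p.cost - a.cost) * (a.mu - b.mu);
      if (s1 >= s2) h.pop_back(); else break;
    }
    h.push_back(p);
  }
  return h;
}

struct Solver {
  Instance ins;
  double best_cost;
  std::vector<int> best_assign, cur_assign;
  bool have_best;
  long long nodes, node_limit;

  double cost_tol() const {
    return 1e-9 * std::max(1.0, std::fabs(have_best ? best_cost : 1.0));
  }

  static bool lex_smaller(const std::vector<int>& a, const std::vector<int>& b) {
    for (size_t i = 0; i < a.size(); ++i) {
      if (a[i] != b[i]) return a[i] < b[i];
    }
    return false;
  }

  // Install a full assignment if strictly cheaper, or equal-cost but
  // lexicographically smaller (the tie-break contract).
  void offer(const std::vector<int>& assign, double cost) {
    if (!have_best || cost < best_cost - cost_tol()) {
      best_cost = cost; best_assign = assign; have_best = true;
    } else if (std::fabs(cost - best_cost) <= cost_tol() &&
               lex_smaller(assign, best_assign)) {
      best_cost = std::min(best_cost, cost); best_assign = assign;
    }
  }

  // Initial incumbent: start every patient at the cheapest hull point and
  // apply whole hull segments in global slope order until feasible. At most
  // one segment beyond the LP optimum, so pruning is tight from the start.
  void greedy_incumbent() {
    std::vector<int> level(ins.P, 0);
    double mu_tot = ins.suf_base_mu[0], cost_tot = ins.suf_base_cost[0];
    for (const Seg& s : ins.segs) {
      if (mu_tot <= ins.cap + CAP_TOL) break;
      ++level[s.patient];
      mu_tot -= s.dmu;
      cost_tot += s.dcost;
    }
    if (mu_tot > ins.cap + CAP_TOL) return;  // cannot happen when feasible
    std::vector<int> assign(ins.P);
    for (int p = 0; p < ins.P; ++p) assign[p] = ins.hull[p][level[p]].idx;
    offer(assign, cost_tot);
  }

  // LP lower bound on completing patients d..P-1 given remaining capacity.
  // Returns +inf when even the min-mu completion is infeasible, and bails
  // out early once the bound exceeds `cutoff` (the value at which the node
  // will be pruned anyway).
  double bound(int d, double cap_rest,
               double cutoff = std::numeric_limits<double>::infinity()) const {
    if (d >= ins.P) return 0.0;
    if (ins.suf_min_mu[d] > cap_rest + CAP_TOL)
      return std::numeric_limits<double>::infinity();
    double need = ins.suf_base_mu[d] - cap_rest;
    double b = ins.suf_base_cost[d];
    if (need <= 0) return b;
    for (const Seg& s : ins.segs) {
      if (s.patient < d) continue;
      if (s.dmu >= need) { b += need * s.slope; need = 0; break; }
      b += s.dcost;
      need -= s.dmu;
      if (b > cutoff) return std::numeric_limits<double>::infinity();
    }
    if (need > 0) return std::numeric_limits<double>::infinity();
    return b;
  }

  // Lexicographically smallest min-cost completion of patients d..P-1,
  // assuming suf_base_mu[d] <= cap_rest + CAP_TOL (min-cost completion
  // feasible). Chooses per patient the lowest-index min-cost plan whose mu
  // leaves the rest feasible.
  void close_with_cheapest(int d, double cap_rest, double cost_fixed) {
    double cand = cost_fixed + ins.suf_base_cost[d];
    if (have_best && cand > best_cost + cost_tol()) return;
    std::vector<int> assign = cur_assign;
    double rest = cap_rest;
    for (int p = d; p < ins.P; ++p) {
      const std::vector<Plan>& kp = ins.kept[p];
      double minc = kp.front().cost;
      double suf_next = (p + 1 < ins.P) ? ins.suf_base_mu[p + 1] : 0.0;
      int chosen = -1; double chosen_mu = 0;
      // kept is sorted by (cost, idx); min-cost plans come first in idx order
      for (const Plan& pl : kp) {
        if (pl.cost > minc) break;
        if (pl.mu + suf_next <= rest + CAP_TOL) {
          chosen = pl.idx; chosen_mu = pl.mu; break;
        }
      }
      if (chosen < 0) return;  // defensive; cannot happen when base feasible
      assign[p] = chosen;
      rest -= chosen_mu;
    }
    offer(assign, cand);
  }

  void dfs(int d, double mu_fixed, double cost_fixed) {
    if (++nodes > node_limit)
      stop("mckp solver: node limit exceeded");
    double cap_rest = ins.cap - mu_fixed;
    if (d == ins.P) {
      if (cap_rest < -CAP_TOL) return;
      offer(cur_assign, cost_fixed);
      return;
    }
    // If the lexicographic cheapest completion fits, it is optimal here.
    if (ins.suf_lex_mu[d] <= cap_rest + CAP_TOL) {
      close_with_cheapest(d, cap_rest, cost_fixed);
      return;
    }
    // Otherwise branch on patient d. Children are explored in ascending
    // LP-bound order (most promising first, so the incumbent tightens
    // quickly); equal-cost tie-breaking is handled by offer(), not by the
    // exploration order.
    struct Child { double b, mu2, cost2; int idx; };
    std::vector<Child> children;
    children.reserve(ins.kept[d].size());
    for (const Plan& pl : ins.kept[d]) {
      double mu2 = mu_fixed + pl.mu, cost2 = cost_fixed + pl.cost;
      if (d + 1 == ins.P && ins.cap - mu2 < -CAP_TOL) continue;
      double cutoff = have_best ?
        best_cost + cost_tol() - cost2 : std::numeric_limits<double>::infinity();
      double b = cost2 + bound(d + 1, ins.cap - mu2, cutoff);
      if (!std::isfinite(b)) continue;
      if (have_best && b > best_cost + cost_tol()) continue;
      children.push_back({b, mu2, cost2, pl.idx});
    }
    std::sort(children.begin(), children.end(),
              [](const Child& a, const Child& b) {
                if (a.b != b.b) return a.b < b.b;
                return a.idx < b.idx;
              });
    for (const Child& ch : children) {
      if (have_best && ch.b > best_cost + cost_tol()) continue;  // re-check
      cur_assign[d] = ch.idx;
      dfs(d + 1, ch.mu2, ch.cost2);
      cur_assign[d] = -1;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List solve_mckp_cpp(NumericMatrix cost, NumericMatrix mu, double cap,
                    double node_limit = 5e7) {
  int P = cost.nrow(), K = cost.ncol();
  if (mu.nrow() != P || mu.ncol() != K)
    stop("cost and mu matrices must have identical shape");
  Instance ins;
  ins.P = P; ins.cap = cap;
  ins.kept.resize(P); ins.hull.resize(P);
  ins.suf_base_cost.assign(P + 1, 0.0);
  ins.suf_base_mu.assign(P + 1, 0.0);
  ins.suf_min_mu.assign(P + 1, 0.0);
  ins.suf_lex_cost.assign(P + 1, 0.0);
  ins.suf_lex_mu.assign(P + 1, 0.0);
  ins.lex_plan.assign(P, -1);

  double total_min_mu = 0.0;
  for (int p = 0; p < P; ++p) {
    std::vector<Plan> all(K);
    for (int k = 0; k < K; ++k) {
      all[k].cost = cost(p, k); all[k].mu = mu(p, k); all[k].idx = k;
      if (!std::isfinite(all[k].cost) || !std::isfinite(all[k].mu) ||
          all[k].mu < 0)
        stop("costs and means must be finite and means non-negative");
    }
    ins.kept[p] = keep_nondominated(all);
    ins.hull[p] = convex_hull(all);
    double mn = all[0].mu;
    for (int k = 1; k < K; ++k) mn = std::min(mn, all[k].mu);
    total_min_mu += mn;
    ins.suf_min_mu[p] = mn;  // temporarily per-patient; suffixed below
  }

  // Infeasible outright?
  if (total_min_mu > cap + CAP_TOL) {
    return List::create(_["feasible"] = false,
                        _["assignment"] = IntegerVector(0),
                        _["total_cost"] = NA_REAL, _["total_mu"] = NA_REAL,
                        _["margin"] = total_min_mu - cap);
  }

  // Suffix sums and segment list.
  for (int p = P - 1; p >= 0; --p) {
    const Plan& h0 = ins.hull[p].front();          // cheapest frontier plan
    const Plan& lex0 = ins.kept[p].front();        // cheapest, lowest index
    ins.lex_plan[p] = lex0.idx;
    ins.suf_base_cost[p] = ins.suf_base_cost[p + 1] + h0.cost;
    ins.suf_base_mu[p]   = ins.suf_base_mu[p + 1] + h0.mu;
    ins.suf_min_mu[p]    = ins.suf_min_mu[p + 1] + ins.suf_min_mu[p];
    ins.suf_lex_cost[p]  = ins.suf_lex_cost[p + 1] + lex0.cost;
    ins.suf_lex_mu[p]    = ins.suf_lex_mu[p + 1] + lex0.mu;
    for (size_t i = 0; i + 1 < ins.hull[p].size(); ++i) {
      const Plan &a = ins.hull[p][i], &b = ins.hull[p][i + 1];
      Seg s;
      s.dmu = a.mu - b.mu; s.dcost = b.cost - a.cost;
      s.slope = (s.dmu > 0) ? s.dcost / s.dmu : 0.0;
      s.patient = p;
      if (s.dmu > 0) ins.segs.push_back(s);
    }
  }
  std::sort(ins.segs.begin(), ins.segs.end(),
            [](const Seg& a, const Seg& b) { return a.slope < b.slope; });

  Solver sol;
  sol.ins = ins;
  sol.best_cost = std::numeric_limits<double>::infinity();
  sol.have_best = false;
  sol.cur_assign.assign(P, -1);
  sol.best_assign.assign(P, -1);
  sol.nodes = 0;
  sol.node_limit = (long long) node_limit;
  sol.greedy_incumbent();
  sol.dfs(0, 0.0, 0.0);

  if (!sol.have_best)   // defensive: feasibility was established above
    return List::create(_["feasible"] = false,
                        _["assignment"] = IntegerVector(0),
                        _["total_cost"] = NA_REAL, _["total_mu"] = NA_REAL,
                        _["margin"] = total_min_mu - cap);

  IntegerVector assign(P);
  double tmu = 0.0, tcost = 0.0;
  for (int p = 0; p < P; ++p) {
    assign[p] = sol.best_assign[p] + 1;  // 1-based
    tmu += mu(p, sol.best_assign[p]);
    tcost += cost(p, sol.best_assign[p]);
  }
  return List::create(_["feasible"] = true, _["assignment"] = assign,
                      _["total_cost"] = tcost, _["total_mu"] = tmu,
                      _["margin"] = 0.0, _["nodes"] = (double) sol.nodes);
}
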