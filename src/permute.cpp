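#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Markov-chain permutation engines for the Manly/Bejder tests. Both chains
// start at the observed data, make `trials` elementary swap attempts between
// saved statistic evaluations (after `burn_in` initial attempts), and save
// `n_perm` cumulative states. The swap proposal is uniform-with-rejection:
// a candidate move is drawn uniformly and discarded if illegal.

static inline int unif_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline bool contains(const std::vector<int>& v, int x) {
  for (size_t k = 0; k < v.size(); ++k) if (v[k] == x) return true;
  return false;
}

// day-level association counts from current group memberships
static void day_cooccurrence(const std::vector<std::vector<int> >& members,
                             const std::vector<std::vector<int> >& day_groups,
                             int n_ind,
                             std::vector<int>& x,          // n x n flat
                             std::vector<double>& assoc_sum) { // per ind
  std::fill(x.begin(), x.end(), 0);
  std::fill(assoc_sum.begin(), assoc_sum.end(), 0.0);
  std::vector<char> co((size_t)n_ind * n_ind);
  for (size_t d = 0; d < day_groups.size(); ++d) {
    std::fill(co.begin(), co.end(), 0);
    for (size_t g = 0; g < day_groups[d].size(); ++g) {
      const std::vector<int>& m = members[day_groups[d][g]];
      for (size_t a = 0; a < m.size(); ++a)
        for (size_t b = a + 1; b < m.size(); ++b) {
          co[(size_t)m[a] * n_ind + m[b]] = 1;
          co[(size_t)m[b] * n_ind + m[a]] = 1;
        }
    }
    for (int i = 0; i < n_ind; ++i) {
      int cnt = 0;
      for (int j = 0; j < n_ind; ++j) {
        if (co[(size_t)i * n_ind + j]) {
          ++cnt;
          if (j > i) ++x[(size_t)i * n_ind + j];
        }
      }
      assoc_sum[i] += cnt;
    }
  }
}

// statistics on the SRI built from x / d over unmasked dyads:
// [0] cv_sri, [1] mean_sri, [2] sd of mean daily associates
static void sri_stats(const std::vector<int>& x, const IntegerMatrix& d,
                      const std::vector<double>& assoc_sum,
                      const IntegerVector& days_seen, int n_ind,
                      double out[3]) {
  double s = 0, s2 = 0;
  long cnt = 0;
  for (int i = 0; i < n_ind; ++i)
    for (int j = i + 1; j < n_ind; ++j) {
      int dd = d(i, j);
      if (dd > 0) {
        double v = (double)x[(size_t)i * n_ind + j] / dd;
        s += v; s2 += v * v; ++cnt;
      }
    }
  double mean = cnt > 0 ? s / cnt : 0.0;
  double varr = cnt > 1 ? (s2 - cnt * mean * mean) / (cnt - 1) : 0.0;
  if (varr < 0) varr = 0;
  out[0] = mean > 0 ? std::sqrt(varr) / mean : 0.0;
  out[1] = mean;
  double gs = 0, gs2 = 0;
  int gn = 0;
  for (int i = 0; i < n_ind; ++i) {
    if (days_seen[i] > 0) {
      double g = assoc_sum[i] / days_seen[i];
      gs += g; gs2 += g * g; ++gn;
    }
  }
  double gmean = gn > 0 ? gs / gn : 0.0;
  double gvar = gn > 1 ? (gs2 - gn * gmean * gmean) / (gn - 1) : 0.0;
  out[2] = gvar > 0 ? std::sqrt(gvar) : 0.0;
}

// group-swap chain: preserves each individual's number of groups per day and
// every group's size
// [[Rcpp::export]]
List cpp_group_chain(List group_members, IntegerVector group_day, int n_ind,
                     IntegerMatrix d, IntegerVector days_seen,
                     int n_perm, int trials, int burn_in) {
  int n_groups = group_members.size();
  std::vector<std::vector<int> > members(n_groups);
  int n_days = 0;
  for (int g = 0; g < n_groups; ++g) {
    IntegerVector m = group_members[g];
    members[g] = std::vector<int>(m.begin(), m.end());
    if (group_day[g] + 1 > n_days) n_days = group_day[g] + 1;
  }
  std::vector<std::vector<int> > day_groups(n_days);
  for (int g = 0; g < n_groups; ++g) day_groups[group_day[g]].push_back(g);
  std::vector<int> eligible;
  for (int dd = 0; dd < n_days; ++dd)
    if (day_groups[dd].size() >= 2) eligible.push_back(dd);

  // a legal swap exists iff some same-day group pair has a member unique to
  // each side
  bool any_legal = false;
  for (size_t e = 0; e < eligible.size() && !any_legal; ++e) {
    const std::vector<int>& gs = day_groups[eligible[e]];
    for (size_t a = 0; a < gs.size() && !any_legal; ++a)
      for (size_t b = a + 1; b < gs.size() && !any_legal; ++b) {
        bool left = false, right = false;
        for (size_t k = 0; k < members[gs[a]].size(); ++k)
          if (!contains(members[gs[b]], members[gs[a]][k])) { left = true; break; }
        for (size_t k = 0; k < members[gs[b]].size(); ++k)
          if (!contains(members[gs[a]], members[gs[b]][k])) { right = true; break; }
        if (left && right) any_legal = true;
      }
  }

  std::vector<int> x((size_t)n_ind * n_ind);
  std::vector<double> assoc_sum(n_ind);
  day_cooccurrence(members, day_groups, n_ind, x, assoc_sum);
  double obs[3];
  sri_stats(x, d, assoc_sum, days_seen, n_ind, obs);
  NumericVector observed = NumericVector::create(obs[0], obs[1], obs[2]);

  if (!any_legal) {
    return List::create(_["observed"] = observed,
                        _["null"] = R_NilValue,
                        _["degenerate"] = true, _["swaps"] = 0);
  }

  long swaps = 0;
  NumericMatrix nullmat(n_perm, 3);
  long total = (long)burn_in + (long)n_perm * trials;
  long next_save = burn_in + trials;
  int saved = 0;
  for (long t = 1; t <= total; ++t) {
    int dd = eligible[unif_index((int)eligible.size())];
    const std::vector<int>& gs = day_groups[dd];
    int a = unif_index((int)gs.size());
    int b = unif_index((int)gs.size());
    if (a != b) {
      std::vector<int>& g1 = members[gs[a]];
      std::vector<int>& g2 = members[gs[b]];
      int ia = unif_index((int)g1.size());
      int ib = unif_index((int)g2.size());
      int va = g1[ia], vb = g2[ib];
      if (!contains(g2, va) && !contains(g1, vb)) {
        g1[ia] = vb;
        g2[ib] = va;
        ++swaps;
      }
    }
    if (t == next_save) {
      day_cooccurrence(members, day_groups, n_ind, x, assoc_sum);
      double st[3];
      sri_stats(x, d, assoc_sum, days_seen, n_ind, st);
      nullmat(saved, 0) = st[0];
      nullmat(saved, 1) = st[1];
      nullmat(saved, 2) = st[2];
      ++saved;
      next_save += trials;
      if (saved == n_perm) break;
    }
  }
  List final_members(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    final_members[g] = IntegerVector(members[g].begin(), members[g].end());
  }
  return List::create(_["observed"] = observed, _["null"] = nullmat,
                      _["degenerate"] = false, _["swaps"] = (double)swaps,
                      _["final_members"] = final_members);
}

// association-swap chain over day-level dyadic records: two same-day records
// with four distinct individuals exchange partners, preserving each
// individual's number of daily associations
// [[Rcpp::export]]
List cpp_assoc_chain(IntegerVector e_day, IntegerVector e_i, IntegerVector e_j,
                     int n_ind, IntegerMatrix d,
                     int n_perm, int trials, int burn_in) {
  int n_edge = e_day.size();
  int n_days = 0;
  for (int k = 0; k < n_edge; ++k)
    if (e_day[k] + 1 > n_days) n_days = e_day[k] + 1;
  std::vector<std::vector<int> > day_edges(n_days);
  std::vector<int> ei(e_i.begin(), e_i.end()), ej(e_j.begin(), e_j.end());
  for (int k = 0; k < n_edge; ++k) day_edges[e_day[k]].push_back(k);
  std::vector<int> eligible;
  for (int dd = 0; dd < n_days; ++dd)
    if (day_edges[dd].size() >= 2) eligible.push_back(dd);

  std::vector<int> x((size_t)n_ind * n_ind);
  for (int k = 0; k < n_edge; ++k) {
    int i = std::min(ei[k], ej[k]), j = std::max(ei[k], ej[k]);
    ++x[(size_t)i * n_ind + j];
  }
  // cv of sri over unmasked dyads (gregariousness terms unused here)
  std::vector<double> dummy_sum(n_ind, 0.0);
  IntegerVector dummy_seen(n_ind, 1);
  double obs[3];
  sri_stats(x, d, dummy_sum, dummy_seen, n_ind, obs);

  // legality scan: two same-day records with four distinct individuals whose
  // crossed pairing creates no duplicate
  bool any_legal = false;
  for (size_t e = 0; e < eligible.size() && !any_legal; ++e) {
    const std::vector<int>& es = day_edges[eligible[e]];
    for (size_t a = 0; a < es.size() && !any_legal; ++a)
      for (size_t b = a + 1; b < es.size() && !any_legal; ++b) {
        int i1 = ei[es[a]], j1 = ej[es[a]], i2 = ei[es[b]], j2 = ej[es[b]];
        if (i1 == i2 || i1 == j2 || j1 == i2 || j1 == j2) continue;
        // either crossing acceptable if new edges absent that day
        for (int var = 0; var < 2 && !any_legal; ++var) {
          int ni1 = i1, nj1 = var == 0 ? j2 : i2;
          int ni2 = var == 0 ? i2 : j2, nj2 = j1;
          bool dup = false;
          for (size_t k = 0; k < es.size(); ++k) {
            int u = ei[es[k]], v = ej[es[k]];
            if ((u == ni1 && v == nj1) || (u == nj1 && v == ni1) ||
                (u == ni2 && v == nj2) || (u == nj2 && v == ni2)) {
              dup = true; break;
            }
          }
          if (!dup) any_legal = true;
        }
      }
  }
  if (!any_legal) {
    return List::create(_["observed"] = obs[0], _["null"] = R_NilValue,
                        _["degenerate"] = true, _["swaps"] = 0);
  }

  NumericVector nullv(n_perm);
  long swaps = 0;
  long total = (long)burn_in + (long)n_perm * trials;
  long next_save = burn_in + trials;
  int saved = 0;
  for (long t = 1; t <= total; ++t) {
    int dd = eligible[unif_index((int)eligible.size())];
    const std::vector<int>& es = day_edges[dd];
    int a = unif_index((int)es.size());
    int b = unif_index((int)es.size());
    if (a != b) {
      int ka = es[a], kb = es[b];
      int i1 = ei[ka], j1 = ej[ka], i2 = ei[kb], j2 = ej[kb];
      if (i1 != i2 && i1 != j2 && j1 != i2 && j1 != j2) {
        int ni1, nj1, ni2, nj2;
        if (unif_rand() < 0.5) { ni1 = i1; nj1 = j2; ni2 = i2; nj2 = j1; }
        else                   { ni1 = i1; nj1 = i2; ni2 = j2; nj2 = j1; }
        bool dup = false;
        for (size_t k = 0; k < es.size(); ++k) {
          int u = ei[es[k]], v = ej[es[k]];
          if ((u == ni1 && v == nj1) || (u == nj1 && v == ni1) ||
              (u == ni2 && v == nj2) || (u == nj2 && v == ni2)) {
            dup = true; break;
          }
        }
        if (!dup) {
          int lo, hi;
          lo = std::min(i1, j1); hi = std::max(i1, j1);
          --x[(size_t)lo * n_ind + hi];
          lo = std::min(i2, j2); hi = std::max(i2, j2);
          --x[(size_t)lo * n_ind + hi];
          ei[ka] = ni1; ej[ka] = nj1;
          ei[kb] = ni2; ej[kb] = nj2;
          lo = std::min(ni1, nj1); hi = std::max(ni1, nj1);
          ++x[(size_t)lo * n_ind + hi];
          lo = std::min(ni2, nj2); hi = std::max(ni2, nj2);
          ++x[(size_t)lo * n_ind + hi];
          ++swaps;
        }
      }
    }
    if (t == next_save) {
      double st[3];
      sri_stats(x, d, dummy_sum, dummy_seen, n_ind, st);
      nullv[saved] = st[0];
      ++saved;
      next_save += trials;
      if (saved == n_perm) break;
    }
  }
  return List::create(_["observed"] = obs[0], _["null"] = nullv,
                      _["degenerate"] = false, _["swaps"] = (double)swaps,
                      _["final_i"] = IntegerVector(ei.begin(), ei.end()),
                      _["final_j"] = IntegerVector(ej.begin(), ej.end()),
                      _["final_day"] = e_day);
}
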