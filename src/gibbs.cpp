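// Gibbs sampler kernel for the latent-structure posterior.
//
// State: candidate original-network adjacency A over [observed | slots],
// with slot s (0-based) removed at step s, plus the category assignment.
// One sweep = optional fresh rejection draw of the whole removal path,
// Metropolis rewiring of each removal event, and Metropolis swaps of
// category sequences. Uses R's RNG so runs are reproducible under set.seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Kernel {
  int n_obs, T, N, k, m;
  double alpha, gamma;
  std::vector<int> A;          // N x N, column-major
  std::vector<int> assign;     // k x N
  std::vector<double> Pm, logPm, log1mPm;  // N x N link probabilities
  std::vector<double> D;       // T x N degrees before each step
  std::vector<double> Z;       // per-step attack normalizer
  std::vector<double> dvict;   // victim degree per step
  double model_ll, att_ll;
  // profile pooling
  int nbins;
  std::vector<int> upair;      // m x m unordered-pair index (1-based ids)
  std::vector<double> coef;    // radix coefficient per pair id
  std::vector<int> ids;        // N x N profile bin per pair
  const NumericMatrix& P;

  Kernel(const NumericMatrix& P_) : P(P_) {}

  inline int a(int i, int j) const { return A[i + (size_t)N * j]; }
  inline void seta(int i, int j, int v) {
    A[i + (size_t)N * j] = v; A[j + (size_t)N * i] = v;
  }
  inline double w(double d) const {
    if (alpha == 0) return 1.0;
    if (d <= 0) return 0.0;
    return std::pow(d, alpha);
  }
  inline int slot_col(int s) const { return n_obs + s; }

  // partners of slot s: observed nodes and slots removed later
  template <class F> void for_partners(int s, F f) const {
    for (int v = 0; v < n_obs; ++v) f(v);
    for (int t = s + 1; t < T; ++t) f(slot_col(t));
  }

  void rebuild_pmat() {
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) {
        double p = 1.0;
        for (int l = 0; l < k; ++l)
          p *= P(assign[l + (size_t)k * i] - 1, assign[l + (size_t)k * j] - 1);
        size_t idx = i + (size_t)N * j;
        Pm[idx] = p; logPm[idx] = std::log(p); log1mPm[idx] = std::log1p(-p);
      }
  }

  void rebuild_ids() {
    if (nbins <= 0) return;
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) {
        double id = 0;
        for (int l = 0; l < k; ++l) {
          int ci = assign[l + (size_t)k * i], cj = assign[l + (size_t)k * j];
          id += coef[upair[(ci - 1) + m * (cj - 1)] - 1];
        }
        ids[i + (size_t)N * j] = (int)(id + 0.5);
      }
  }

  void rebuild_model_ll() {
    double s = 0;
    for (int j = 1; j < N; ++j)
      for (int i = 0; i < j; ++i) {
        size_t idx = i + (size_t)N * j;
        s += a(i, j) ? logPm[idx] : log1mPm[idx];
      }
    model_ll = s;
  }

  // Rebuild attack caches from A. Returns false if some victim has zero
  // degree at its removal time (zero-mass trajectory).
  bool rebuild_attack() {
    std::vector<double> deg(N, 0.0);
    std::vector<char> present(N, 1);
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) deg[j] += a(i, j);
    att_ll = 0;
    bool ok = true;
    for (int s = 0; s < T; ++s) {
      int v = slot_col(s);
      double z = 0;
      for (int u = 0; u < N; ++u) {
        D[s + (size_t)T * u] = present[u] ? deg[u] : 0.0;
        if (present[u]) z += w(deg[u]);
      }
      Z[s] = z;
      dvict[s] = deg[v];
      if (deg[v] <= 0) ok = false;
      else att_ll += alpha * std::log(deg[v]) - std::log(z);
      for (int u = 0; u < N; ++u)
        if (present[u] && a(v, u)) deg[u] -= 1;
      deg[v] = 0;
      present[v] = 0;
    }
    if (!ok) att_ll = R_NegInf;
    return ok;
  }

  // Fresh rejection draw of the whole path: each pass restores the slots in
  // reverse removal order, redrawing a slot's links until its degree is
  // positive (constant per-slot normaliser) and testing the attack
  // transition probability of the restored node; any failed test restarts
  // the entire pass, so accepted paths are exact draws from the trajectory
  // posterior. Returns true on success (A and caches updated), false when
  // `budget` passes are exhausted (state left unchanged).
  bool fresh_draw(int budget) {
    if (budget <= 0 || T == 0) return false;
    std::vector<double> deg0(N, 0.0);
    for (int j = 0; j < n_obs; ++j)
      for (int i = 0; i < n_obs; ++i) deg0[j] += a(i, j);
    bool const_acc = (gamma == 0 || alpha == 0);
    std::vector<std::vector<int> > links(T);
    std::vector<double> deg(N);
    for (int pass = 0; pass < budget; ++pass) {
      deg = deg0;
      bool ok = true;
      for (int s = T - 1; s >= 0 && ok; --s) {
        int i = slot_col(s);
        std::vector<int> partners;
        for_partners(s, [&](int v) { partners.push_back(v); });
        int np = partners.size();
        std::vector<int> li(np);
        double d = 0;
        for (int trial = 0; trial < 200; ++trial) {
          d = 0;
          for (int x = 0; x < np; ++x) {
            li[x] = (unif_rand() < Pm[i + (size_t)N * partners[x]]) ? 1 : 0;
            d += li[x];
          }
          if (d > 0) break;
        }
        if (d == 0) { ok = false; break; }
        if (!const_acc) {
          double z = w(d);
          for (int x = 0; x < np; ++x) z += w(deg[partners[x]] + li[x]);
          double acc = std::exp(gamma * (alpha * std::log(d) - std::log(z)));
          if (unif_rand() >= acc) { ok = false; break; }
        }
        for (int x = 0; x < np; ++x) deg[partners[x]] += li[x];
        deg[i] = d;
        links[s] = li;
      }
      if (!ok) continue;
      // commit: clear slot-incident entries, write the new links
      for (int s = 0; s < T; ++s) {
        int i = slot_col(s);
        for (int v = 0; v < N; ++v) seta(i, v, 0);
      }
      for (int s = 0; s < T; ++s) {
        int i = slot_col(s), x = 0;
        for_partners(s, [&](int v) {
          if (links[s][x]) seta(i, v, 1);
          ++x;
        });
      }
      rebuild_model_ll();
      rebuild_attack();
      return true;
    }
    return false;
  }

  void refine(int n_steps) {
    std::vector<int> partners, nbrs, elig;
    std::vector<double> zbuf(T);
    for (int s = 0; s < T; ++s) {
      int i = slot_col(s);
      partners.clear();
      for_partners(s, [&](int v) { partners.push_back(v); });
      for (int rep = 0; rep < n_steps; ++rep) {
        nbrs.clear();
        for (size_t x = 0; x < partners.size(); ++x)
          if (a(i, partners[x])) nbrs.push_back(partners[x]);
        int d = nbrs.size();
        if (d == 0) break;
        int j = nbrs[(int)(unif_rand() * d) % d];
        elig.clear();
        double tot = 0;
        for (size_t x = 0; x < partners.size(); ++x) {
          int v = partners[x];
          if (!a(i, v) || v == j) {
            elig.push_back(v);
            tot += Pm[i + (size_t)N * v];
          }
        }
        double u = unif_rand() * tot, cum = 0;
        int jp = elig.back();
        for (size_t x = 0; x < elig.size(); ++x) {
          cum += Pm[i + (size_t)N * elig[x]];
          if (u <= cum) { jp = elig[x]; break; }
        }
        if (jp == j) continue;
        size_t ij = i + (size_t)N * j, ijp = i + (size_t)N * jp;
        double dmodel = logPm[ijp] - log1mPm[ijp] - logPm[ij] + log1mPm[ij];
        double datt = 0;
        if (alpha != 0) {
          for (int r = 0; r <= s; ++r) {
            double dj = D[r + (size_t)T * j], djp = D[r + (size_t)T * jp];
            double zr = Z[r] - w(dj) + w(dj - 1) - w(djp) + w(djp + 1);
            zbuf[r] = zr;
            datt -= std::log(zr) - std::log(Z[r]);
          }
        }
        double lr = dmodel + gamma * datt + logPm[ij] - logPm[ijp];
        if (std::log(unif_rand()) < lr) {
          seta(i, j, 0);
          seta(i, jp, 1);
          model_ll += dmodel;
          if (alpha != 0) {
            att_ll += datt;
            for (int r = 0; r <= s; ++r) {
              D[r + (size_t)T * j] -= 1;
              D[r + (size_t)T * jp] += 1;
              Z[r] = zbuf[r];
            }
          }
        }
      }
    }
  }

  // Degree-changing complement of the rewiring chain: toggle one link
  // between the restored node of event s and a uniformly chosen present
  // node, accepted with the full-conditional Metropolis ratio. Removing a
  // node's last link is rejected (zero-mass state).
  void toggles(int n_steps) {
    std::vector<int> partners;
    std::vector<double> zbuf(T);
    for (int s = 0; s < T; ++s) {
      int i = slot_col(s);
      partners.clear();
      for_partners(s, [&](int v) { partners.push_back(v); });
      int np = partners.size();
      if (np == 0) continue;
      for (int rep = 0; rep < n_steps; ++rep) {
        int u = partners[(int)(unif_rand() * np) % np];
        bool adding = !a(i, u);
        double d = dvict[s];
        if (!adding && d <= 1) continue;
        double dnew = adding ? d + 1 : d - 1;
        size_t iu = i + (size_t)N * u;
        double dmodel = adding ? (logPm[iu] - log1mPm[iu])
                               : (log1mPm[iu] - logPm[iu]);
        double datt = 0;
        if (alpha != 0) {
          double sgn = adding ? 1.0 : -1.0;
          datt += alpha * (std::log(dnew) - std::log(d));
          for (int r = 0; r <= s; ++r) {
            double du = D[r + (size_t)T * u], di = D[r + (size_t)T * i];
            double zr = Z[r] - w(du) + w(du + sgn) - w(di) + w(di + sgn);
            zbuf[r] = zr;
            datt -= std::log(zr) - std::log(Z[r]);
          }
        }
        double lr = dmodel + gamma * datt;
        if (std::log(unif_rand()) < lr) {
          seta(i, u, adding ? 1 : 0);
          model_ll += dmodel;
          if (alpha != 0) {
            att_ll += datt;
            double sgn = adding ? 1.0 : -1.0;
            for (int r = 0; r <= s; ++r) {
              D[r + (size_t)T * u] += sgn;
              D[r + (size_t)T * i] += sgn;
              Z[r] = zbuf[r];
            }
          }
          dvict[s] = dnew;
        }
      }
    }
  }

  void swaps(int n_steps) {
    for (int it = 0; it < n_steps; ++it) {
      int i = (int)(unif_rand() * N) % N;
      int j = (int)(unif_rand() * (N - 1)) % (N - 1);
      if (j >= i) ++j;
      bool same = true;
      for (int l = 0; l < k; ++l)
        if (assign[l + (size_t)k * i] != assign[l + (size_t)k * j]) {
          same = false; break;
        }
      if (same) continue;
      double dl = 0;
      for (int v = 0; v < N; ++v) {
        if (v == i || v == j) continue;
        int ai = a(i, v), aj = a(j, v);
        if (ai == aj) continue;
        size_t iv = i + (size_t)N * v, jv = j + (size_t)N * v;
        dl += (ai - aj) *
              ((logPm[jv] - logPm[iv]) - (log1mPm[jv] - log1mPm[iv]));
      }
      if (std::log(unif_rand()) < dl) {
        for (int l = 0; l < k; ++l)
          std::swap(assign[l + (size_t)k * i], assign[l + (size_t)k * j]);
        swap_rows_cols(Pm, i, j);
        swap_rows_cols(logPm, i, j);
        swap_rows_cols(log1mPm, i, j);
        if (nbins > 0) swap_rows_cols_int(ids, i, j);
        model_ll += dl;
      }
    }
  }

  void swap_rows_cols(std::vector<double>& M, int i, int j) {
    for (int v = 0; v < N; ++v)
      std::swap(M[i + (size_t)N * v], M[j + (size_t)N * v]);
    for (int v = 0; v < N; ++v)
      std::swap(M[v + (size_t)N * i], M[v + (size_t)N * j]);
  }
  void swap_rows_cols_int(std::vector<int>& M, int i, int j) {
    for (int v = 0; v < N; ++v)
      std::swap(M[i + (size_t)N * v], M[j + (size_t)N * v]);
    for (int v = 0; v < N; ++v)
      std::swap(M[v + (size_t)N * i], M[v + (size_t)N * j]);
  }
};

}  // namespace

// [[Rcpp::export]]
List gibbs_kernel(IntegerMatrix A_init, IntegerMatrix assign_init,
                  NumericMatrix P, int n_obs, int T, double alpha,
                  double gamma, int K, int B, int refine_steps,
                  int toggle_steps, int swap_steps, int proposal_budget,
                  int nbins,
                  IntegerMatrix upair, NumericVector coef,
                  bool keep_samples) {
  Kernel kn(P);
  kn.n_obs = n_obs; kn.T = T; kn.N = n_obs + T;
  kn.k = assign_init.nrow(); kn.m = P.nrow();
  kn.alpha = alpha; kn.gamma = gamma;
  int N = kn.N;
  kn.A.assign(A_init.begin(), A_init.end());
  kn.assign.assign(assign_init.begin(), assign_init.end());
  kn.Pm.resize((size_t)N * N); kn.logPm.resize((size_t)N * N);
  kn.log1mPm.resize((size_t)N * N);
  kn.D.assign((size_t)std::max(T, 1) * N, 0.0);
  kn.Z.assign(std::max(T, 1), 0.0);
  kn.dvict.assign(std::max(T, 1), 0.0);
  kn.nbins = nbins;
  if (nbins > 0) {
    kn.upair.assign(upair.begin(), upair.end());
    kn.coef.assign(coef.begin(), coef.end());
    kn.ids.assign((size_t)N * N, 0);
  }
  kn.rebuild_pmat();
  kn.rebuild_ids();
  kn.rebuild_model_ll();
  kn.rebuild_attack();

  List slot_links(keep_samples ? K : 0);
  List assigns(keep_samples ? K : 0);
  NumericVector model_v(K), att_v(K), complete_v(K);
  NumericMatrix link_sum(std::max(T, 1), N);
  std::vector<double> edge_cnt, nonedge_cnt;
  if (nbins > 0) {
    edge_cnt.assign(nbins, 0.0);
    nonedge_cnt.assign(nbins, 0.0);
  }
  int fresh_ok = 0;
  int rec = 0;
  double best_ll = R_NegInf;
  IntegerMatrix best_slots(std::max(T, 1), N);
  IntegerMatrix best_assign(kn.k, N);
  for (int sweep = 0; sweep < B + K; ++sweep) {
    if ((sweep & 1023) == 1023) {  // guard against float drift
      kn.rebuild_model_ll();
      kn.rebuild_attack();
    }
    if (proposal_budget > 0 && kn.fresh_draw(proposal_budget)) ++fresh_ok;
    if (toggle_steps > 0) kn.toggles(toggle_steps);
    if (refine_steps > 0) kn.refine(refine_steps);
    if (swap_steps > 0) kn.swaps(swap_steps);
    if (sweep >= B) {
      model_v[rec] = kn.model_ll;
      att_v[rec] = kn.att_ll;
      complete_v[rec] = R_finite(kn.att_ll)
        ? kn.model_ll + gamma * kn.att_ll : R_NegInf;
      for (int s = 0; s < T; ++s)
        for (int v = 0; v < N; ++v)
          link_sum(s, v) += kn.a(kn.slot_col(s), v);
      if (keep_samples) {
        IntegerMatrix sl(std::max(T, 1), N);
        for (int s = 0; s < T; ++s)
          for (int v = 0; v < N; ++v) sl(s, v) = kn.a(kn.slot_col(s), v);
        IntegerMatrix am(kn.k, N);
        std::copy(kn.assign.begin(), kn.assign.end(), am.begin());
        slot_links[rec] = sl;
        assigns[rec] = am;
      }
      if (nbins > 0) {
        for (int j = 1; j < N; ++j)
          for (int i = 0; i < j; ++i) {
            int bin = kn.ids[i + (size_t)N * j];
            if (kn.a(i, j)) edge_cnt[bin] += 1;
            else nonedge_cnt[bin] += 1;
          }
      }
      if (complete_v[rec] > best_ll) {
        best_ll = complete_v[rec];
        for (int s = 0; s < T; ++s)
          for (int v = 0; v < N; ++v)
            best_slots(s, v) = kn.a(kn.slot_col(s), v);
        std::copy(kn.assign.begin(), kn.assign.end(), best_assign.begin());
      }
      ++rec;
    }
  }
  IntegerMatrix finalA(N, N);
  std::copy(kn.A.begin(), kn.A.end(), finalA.begin());
  IntegerMatrix finalAssign(kn.k, N);
  std::copy(kn.assign.begin(), kn.assign.end(), finalAssign.begin());
  List out = List::create(
      Named("slot_links") = slot_links, Named("assigns") = assigns,
      Named("model_ll") = model_v, Named("attack_ll") = att_v,
      Named("complete_ll") = complete_v, Named("link_sum") = link_sum,
      Named("final_A") = finalA, Named("final_assign") = finalAssign,
      Named("fresh_success") = fresh_ok, Named("best_ll") = best_ll,
      Named("best_slots") = best_slots, Named("best_assign") = best_assign);
  if (nbins > 0) {
    out["edge_counts"] = NumericVector(edge_cnt.begin(), edge_cnt.end());
    out["nonedge_counts"] = NumericVector(nonedge_cnt.begin(), nonedge_cnt.end());
  }
  return out;
}
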