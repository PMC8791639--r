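// Core scanning engine: sigma70-RNAP binding-configuration enumeration,
// occupancy (P_on) evaluation, multinomial-logistic log-likelihood with
// analytic gradients, dinucleotide-interaction screening, and the
// genome-wide free-energy track.
//
// Geometry (0-based): a configuration at forward offset o with spacer s
// contacts positions [o, o+L35) with the upstream block and
// [o+L35+s, o+L35+s+L10) with the downstream block.  Its "-10 end" is the
// last downstream contact, o + L35 + s + L10 - 1.  Contact index k in
// [0, L35+L10) maps to sequence position o+k (k < L35) or o+L35+s+(k-L35).
//
// Classes: 0 = productive, 1 = occlusive unproductive (forward, -10 end
// within the RBS occlusion cutoff), 2 = reverse-complement unproductive.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LN10 = 2.302585092994046;

// log(1 / (R + exp(t))) computed stably for any t.
static inline double log_weight(double t, double R) {
  if (t > 35.0) return -t - std::log1p(R * std::exp(-t));
  return -std::log(R + std::exp(t));
}

// log(1 + exp(t)) stably.
static inline double log1p_exp(double t) {
  if (t > 35.0) return t + std::exp(-t);
  return std::log1p(std::exp(t));
}

struct ModelView {
  const double *up;     // 4 x L35, column-major
  const double *down;   // 4 x L10
  int L35, L10;
  const int *spacers;   // increasing spacer lengths
  const double *spen;   // penalties per spacer
  int n_sp;
  const int *dn;        // n_dn x 4 (pos_i, base_i, pos_j, base_j), col-major
  const double *dnde;
  int n_dn;
  double mu, R;
  int cutoff;
};

// Energy of one configuration on coded strand `c` (length L).
static inline double config_energy(const int *c, int o, int s_idx,
                                   const ModelView &m, bool use_spen,
                                   bool use_dinuc) {
  int s = m.spacers[s_idx];
  double E = 0.0;
  for (int j = 0; j < m.L35; ++j) E += m.up[4 * j + c[o + j]];
  int od = o + m.L35 + s;
  for (int j = 0; j < m.L10; ++j) E += m.down[4 * j + c[od + j]];
  if (use_spen) E += m.spen[s_idx];
  if (use_dinuc) {
    int nd = m.n_dn;
    for (int d = 0; d < nd; ++d) {
      int pi = m.dn[d], bi = m.dn[nd + d], pj = m.dn[2 * nd + d],
          bj = m.dn[3 * nd + d];
      int posi = (pi < m.L35) ? o + pi : od + (pi - m.L35);
      int posj = (pj < m.L35) ? o + pj : od + (pj - m.L35);
      if (c[posi] == bi && c[posj] == bj) E += m.dnde[d];
    }
  }
  return E;
}

static ModelView make_view(const NumericMatrix &up, const NumericMatrix &down,
                           const IntegerVector &spacers,
                           const NumericVector &spen,
                           const IntegerMatrix &dnpos,
                           const NumericVector &dnde, double mu, double R,
                           int cutoff) {
  ModelView m;
  m.up = up.begin(); m.down = down.begin();
  m.L35 = up.ncol(); m.L10 = down.ncol();
  m.spacers = spacers.begin(); m.spen = spen.begin();
  m.n_sp = spacers.size();
  m.dn = dnpos.begin(); m.dnde = dnde.begin(); m.n_dn = dnpos.nrow();
  m.mu = mu; m.R = R; m.cutoff = cutoff;
  return m;
}

// Enumerate all configurations of one sequence as a table.
// [[Rcpp::export]]
DataFrame cpp_config_table(IntegerVector codes, NumericMatrix up,
                           NumericMatrix down, IntegerVector spacers,
                           NumericVector spen, IntegerMatrix dnpos,
                           NumericVector dnde, double mu, double R,
                           int rbs, int cutoff, bool use_dinuc) {
  ModelView m = make_view(up, down, spacers, spen, dnpos, dnde, mu, R, cutoff);
  int L = codes.size();
  std::vector<int> fwd(codes.begin(), codes.end());
  std::vector<int> rc(L);
  for (int i = 0; i < L; ++i) rc[i] = 3 - fwd[L - 1 - i];

  std::vector<int> v_strand, v_off, v_sp, v_klass;
  std::vector<double> v_E;
  for (int strand = 0; strand < 2; ++strand) {
    const int *c = strand == 0 ? fwd.data() : rc.data();
    int wmin = m.L35 + m.spacers[0] + m.L10;
    for (int o = 0; o + wmin <= L; ++o) {
      for (int si = 0; si < m.n_sp; ++si) {
        int w = m.L35 + m.spacers[si] + m.L10;
        if (o + w > L) continue;
        double E = config_energy(c, o, si, m, true, use_dinuc);
        int klass;
        int off_fwd;
        if (strand == 1) {
          klass = 2;
          off_fwd = L - (o + w);
        } else {
          off_fwd = o;
          klass = 0;
          if (rbs >= 0) {
            int ten_end = o + w - 1;
            int dist = rbs - (ten_end + 1);
            if (dist <= cutoff) klass = 1;
          }
        }
        v_strand.push_back(strand);
        v_off.push_back(off_fwd);
        v_sp.push_back(m.spacers[si]);
        v_E.push_back(E);
        v_klass.push_back(klass);
      }
    }
  }
  return DataFrame::create(_["strand"] = v_strand, _["offset"] = v_off,
                           _["spacer"] = v_sp, _["energy"] = v_E,
                           _["klass"] = v_klass);
}

// Per-sequence scan used by P_on and the likelihood.  Fills scratch arrays
// of (t = E - mu, klass) in a fixed deterministic order.  Upstream- and
// downstream-block sums are cached per offset (each is shared by several
// configurations), which roughly halves the work of a scan.
static void scan_sequence(const int *fwd, int L, const ModelView &m,
                          bool use_spen, bool use_occl, bool use_rc,
                          bool use_dinuc, int rbs,
                          std::vector<double> &ts, std::vector<int> &klass,
                          std::vector<int> &offs, std::vector<int> &sidx,
                          std::vector<int> &strands, std::vector<int> &rcbuf) {
  ts.clear(); klass.clear(); offs.clear(); sidx.clear(); strands.clear();
  int n_strand = use_rc ? 2 : 1;
  if (use_rc) {
    rcbuf.resize(L);
    for (int i = 0; i < L; ++i) rcbuf[i] = 3 - fwd[L - 1 - i];
  }
  int wmin = m.L35 + m.spacers[0] + m.L10;
  static thread_local std::vector<double> up_sum, dn_sum;
  for (int strand = 0; strand < n_strand; ++strand) {
    const int *c = strand == 0 ? fwd : rcbuf.data();
    int n_up = L - m.L35 + 1, n_dn = L - m.L10 + 1;
    if (n_up <= 0 || n_dn <= 0) continue;
    up_sum.assign(n_up, 0.0); dn_sum.assign(n_dn, 0.0);
    for (int o = 0; o < n_up; ++o) {
      double e = 0.0;
      for (int j = 0; j < m.L35; ++j) e += m.up[4 * j + c[o + j]];
      up_sum[o] = e;
    }
    for (int o = 0; o < n_dn; ++o) {
      double e = 0.0;
      for (int j = 0; j < m.L10; ++j) e += m.down[4 * j + c[o + j]];
      dn_sum[o] = e;
    }
    for (int o = 0; o + wmin <= L; ++o) {
      for (int si = 0; si < m.n_sp; ++si) {
        int s = m.spacers[si];
        int w = m.L35 + s + m.L10;
        if (o + w > L) continue;
        double E = up_sum[o] + dn_sum[o + m.L35 + s];
        if (use_spen) E += m.spen[si];
        if (use_dinuc && m.n_dn > 0) {
          int od = o + m.L35 + s, nd = m.n_dn;
          for (int d = 0; d < nd; ++d) {
            int pi = m.dn[d], bi = m.dn[nd + d], pj = m.dn[2 * nd + d],
                bj = m.dn[3 * nd + d];
            int posi = (pi < m.L35) ? o + pi : od + (pi - m.L35);
            int posj = (pj < m.L35) ? o + pj : od + (pj - m.L35);
            if (c[posi] == bi && c[posj] == bj) E += m.dnde[d];
          }
        }
        int kl = 0;
        if (strand == 1) kl = 2;
        else if (use_occl && rbs >= 0) {
          int dist = rbs - (o + w);
          if (dist <= m.cutoff) kl = 1;
        }
        ts.push_back(E - m.mu);
        klass.push_back(kl);
        offs.push_back(o);
        sidx.push_back(si);
        strands.push_back(strand);
      }
    }
  }
}

// log10 P_on for one scanned sequence.  sum_mode: thermodynamic sum with
// unproductive states (Extended family); otherwise single strongest
// productive site (Standard family).  Returns -Inf when no productive
// configuration exists in sum mode.
struct PonResult {
  double x;          // log10 P_on
  double logSon, logD;
  int argmin;        // min-mode: index of the governing configuration
};

static PonResult pon_from_scan(const std::vector<double> &ts,
                               const std::vector<int> &klass,
                               const std::vector<int> &offs,
                               const std::vector<int> &sidx,
                               double R, bool sum_mode) {
  PonResult res; res.argmin = -1;
  int n = ts.size();
  if (!sum_mode) {
    double best = R_PosInf; int bi = -1;
    for (int i = 0; i < n; ++i) {
      if (klass[i] != 0) continue;
      if (ts[i] < best ||
          (ts[i] == best && bi >= 0 &&
           (offs[i] < offs[bi] || (offs[i] == offs[bi] && sidx[i] < sidx[bi])))) {
        best = ts[i]; bi = i;
      }
    }
    res.argmin = bi;
    if (bi < 0) { res.x = R_NegInf; res.logSon = R_NegInf; res.logD = 0; return res; }
    res.x = -log1p_exp(best) / LN10;
    res.logSon = -best; res.logD = log1p_exp(best) - best;
    return res;
  }
  // sum mode: log-sum-exp over log-weights
  double max_on = R_NegInf, max_all = 0.0; // logD includes the "1" state (log 1 = 0)
  std::vector<double> lw(n);
  for (int i = 0; i < n; ++i) {
    lw[i] = log_weight(ts[i], R);
    if (klass[i] == 0 && lw[i] > max_on) max_on = lw[i];
    if (lw[i] > max_all) max_all = lw[i];
  }
  if (max_on == R_NegInf) { res.x = R_NegInf; res.logSon = R_NegInf; res.logD = 0; return res; }
  double s_on = 0.0, s_all = std::exp(0.0 - max_all);
  for (int i = 0; i < n; ++i) {
    if (klass[i] == 0) s_on += std::exp(lw[i] - max_on);
    s_all += std::exp(lw[i] - max_all);
  }
  res.logSon = max_on + std::log(s_on);
  res.logD = max_all + std::log(s_all);
  res.x = (res.logSon - res.logD) / LN10;
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_log10_pon(List seqs, IntegerVector rbs, NumericMatrix up,
                            NumericMatrix down, IntegerVector spacers,
                            NumericVector spen, IntegerMatrix dnpos,
                            NumericVector dnde, double mu, double R,
                            int cutoff, bool sum_mode, bool use_spen,
                            bool use_occl, bool use_rc, bool use_dinuc) {
  ModelView m = make_view(up, down, spacers, spen, dnpos, dnde, mu, R, cutoff);
  int n = seqs.size();
  NumericVector out(n);
  std::vector<double> ts; std::vector<int> kl, offs, sidx, strands, rcbuf;
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    scan_sequence(sq.begin(), sq.size(), m, use_spen, use_occl, use_rc,
                  use_dinuc, rbs[s], ts, kl, offs, sidx, strands, rcbuf);
    out[s] = pon_from_scan(ts, kl, offs, sidx, R, sum_mode).x;
  }
  return out;
}

// Link contribution for one sequence: log-likelihood and d(ll)/dx under the
// normalized per-bin logistic link.
static inline void link_ll_grad(double x, int y, double w, const double *a,
                                const double *b, int B, double &ll, double &g,
                                double *ga = 0, double *gb = 0) {
  // log sigma(z) = -log(1+exp(-z)), computed stably; sums in log space
  double lsig_y = 0.0, sig_y = 0.0, max_ls = R_NegInf;
  std::vector<double> ls(B), sg(B);
  for (int i = 0; i < B; ++i) {
    double z = a[i] * x + b[i];
    double l = (z > -35.0) ? -log1p_exp(-z) : z;
    ls[i] = l;
    sg[i] = std::exp(l);
    if (l > max_ls) max_ls = l;
    if (i == y) { lsig_y = l; sig_y = sg[i]; }
  }
  double se = 0.0;
  for (int i = 0; i < B; ++i) se += std::exp(ls[i] - max_ls);
  double logS = max_ls + std::log(se);
  double gs = 0.0;
  for (int i = 0; i < B; ++i) {
    double Di = ((i == y ? 1.0 : 0.0) - std::exp(ls[i] - logS)) *
                (1.0 - sg[i]);
    gs += a[i] * Di;
    if (ga) { ga[i] += w * Di * x; gb[i] += w * Di; }
  }
  ll = w * (lsig_y - logS);
  g = w * gs;
}

// Weighted multinomial-logistic log-likelihood of the binned data given the
// energy model, with analytic gradients over matrix entries, spacer
// penalties, mu and dinucleotide deltas.
// [[Rcpp::export]]
List cpp_loglik(List seqs, IntegerVector rbs, NumericMatrix up,
                NumericMatrix down, IntegerVector spacers, NumericVector spen,
                IntegerMatrix dnpos, NumericVector dnde, double mu, double R,
                int cutoff, bool sum_mode, bool use_spen, bool use_occl,
                bool use_rc, bool use_dinuc, IntegerVector y,
                NumericVector wgt, NumericVector a, NumericVector b,
                bool want_grad, bool deltas_only) {
  ModelView m = make_view(up, down, spacers, spen, dnpos, dnde, mu, R, cutoff);
  int n = seqs.size(), B = a.size();
  int L35 = m.L35, L10 = m.L10, nd = m.n_dn;
  NumericMatrix g_up(4, L35), g_down(4, L10);
  NumericVector g_spen(m.n_sp), g_delta(std::max(nd, 1));
  NumericVector g_a(B), g_b(B);
  double g_mu = 0.0, ll_tot = 0.0;
  NumericVector xs(n);
  std::vector<double> ts, lw;
  std::vector<int> kl, offs, sidx, strands, rcbuf;

  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    const int *fwd = sq.begin();
    int L = sq.size();
    scan_sequence(fwd, L, m, use_spen, use_occl, use_rc, use_dinuc, rbs[s],
                  ts, kl, offs, sidx, strands, rcbuf);
    PonResult pr = pon_from_scan(ts, kl, offs, sidx, R, sum_mode);
    xs[s] = pr.x;
    if (!R_finite(pr.x)) continue; // no productive state: skip record
    double ll, g;
    link_ll_grad(pr.x, y[s], wgt[s], a.begin(), b.begin(), B, ll, g,
                 want_grad ? g_a.begin() : (double *)0,
                 want_grad ? g_b.begin() : (double *)0);
    ll_tot += ll;
    if (!want_grad) continue;

    int nc = ts.size();
    static thread_local std::vector<double> fa_up[2], fa_dn[2];
    if (!deltas_only)
      for (int st2 = 0; st2 < (use_rc ? 2 : 1); ++st2) {
        fa_up[st2].assign(L, 0.0); fa_dn[st2].assign(L, 0.0);
      }
    double dxdmu_sum = 0.0;
    for (int i = 0; i < nc; ++i) {
      double dxdE;
      if (!sum_mode) {
        if (i != pr.argmin) continue;
        double sig = 1.0 / (1.0 + std::exp(-ts[i]));
        dxdE = -sig / LN10;
      } else {
        double lwi = log_weight(ts[i], R);
        double q = std::exp(lwi - pr.logD);
        double omRw = std::exp(ts[i] + lwi); // u / (R + u)
        if (kl[i] == 0) {
          double r = std::exp(lwi - pr.logSon);
          dxdE = -(r - q) * omRw / LN10;
        } else {
          dxdE = q * omRw / LN10;
        }
      }
      dxdmu_sum += dxdE;
      double f = g * dxdE;
      if (f == 0.0) continue;
      int o = offs[i], si = sidx[i];
      int sp = m.spacers[si];
      int od = o + L35 + sp;
      if (!deltas_only) {
        fa_up[strands[i]][o] += f;
        fa_dn[strands[i]][od] += f;
        if (use_spen) g_spen[si] += f;
      }
      if (use_dinuc && nd > 0) {
        const int *c = strands[i] == 0 ? fwd : rcbuf.data();
        for (int d = 0; d < nd; ++d) {
          int pi = m.dn[d], bi = m.dn[nd + d], pj = m.dn[2 * nd + d],
              bj = m.dn[3 * nd + d];
          int posi = (pi < L35) ? o + pi : od + (pi - L35);
          int posj = (pj < L35) ? o + pj : od + (pj - L35);
          if (c[posi] == bi && c[posj] == bj) g_delta[d] += f;
        }
      }
    }
    if (!deltas_only) {
      for (int st2 = 0; st2 < (use_rc ? 2 : 1); ++st2) {
        const int *c = st2 == 0 ? fwd : rcbuf.data();
        for (int o = 0; o < L; ++o) {
          double f = fa_up[st2][o];
          if (f != 0.0)
            for (int j = 0; j < L35; ++j) g_up(c[o + j], j) += f;
          f = fa_dn[st2][o];
          if (f != 0.0)
            for (int j = 0; j < L10; ++j) g_down(c[o + j], j) += f;
        }
      }
    }
    g_mu += g * (-dxdmu_sum);
  }
  return List::create(_["ll"] = ll_tot, _["x"] = xs, _["grad_up"] = g_up,
                      _["grad_down"] = g_down, _["grad_spacer"] = g_spen,
                      _["grad_mu"] = g_mu, _["grad_delta"] = g_delta,
                      _["grad_a"] = g_a, _["grad_b"] = g_b);
}

// One-pass screening score for every candidate dinucleotide interaction:
// dLL/d(delta_c) evaluated at delta = 0, for all C(L,2)*16 candidates.
// [[Rcpp::export]]
NumericVector cpp_dinuc_score(List seqs, IntegerVector rbs, NumericMatrix up,
                              NumericMatrix down, IntegerVector spacers,
                              NumericVector spen, IntegerMatrix dnpos,
                              NumericVector dnde, double mu, double R,
                              int cutoff, bool use_spen, bool use_occl,
                              bool use_rc, bool use_dinuc, IntegerVector y,
                              NumericVector wgt, NumericVector a,
                              NumericVector b) {
  ModelView m = make_view(up, down, spacers, spen, dnpos, dnde, mu, R, cutoff);
  int n = seqs.size(), B = a.size();
  int nct = m.L35 + m.L10;
  // pair (k < l) base offset into the score vector
  std::vector<int> pair_off(nct * nct, -1);
  int np = 0;
  for (int k = 0; k < nct; ++k)
    for (int l = k + 1; l < nct; ++l) { pair_off[k * nct + l] = np * 16; ++np; }
  NumericVector score(np * 16);
  std::vector<double> ts; std::vector<int> kl, offs, sidx, strands, rcbuf;
  std::vector<int> cbase(nct);

  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    const int *fwd = sq.begin();
    scan_sequence(fwd, sq.size(), m, use_spen, use_occl, use_rc, use_dinuc,
                  rbs[s], ts, kl, offs, sidx, strands, rcbuf);
    PonResult pr = pon_from_scan(ts, kl, offs, sidx, R, true);
    if (!R_finite(pr.x)) continue;
    double ll, g;
    link_ll_grad(pr.x, y[s], wgt[s], a.begin(), b.begin(), B, ll, g);
    int nc = ts.size();
    for (int i = 0; i < nc; ++i) {
      double lwi = log_weight(ts[i], R);
      double q = std::exp(lwi - pr.logD);
      double omRw = std::exp(ts[i] + lwi);
      double dxdE;
      if (kl[i] == 0) {
        double r = std::exp(lwi - pr.logSon);
        dxdE = -(r - q) * omRw / LN10;
      } else {
        dxdE = q * omRw / LN10;
      }
      double f = g * dxdE;
      if (f == 0.0) continue;
      int o = offs[i], sp = m.spacers[sidx[i]];
      const int *c = strands[i] == 0 ? fwd : rcbuf.data();
      int od = o + m.L35 + sp;
      for (int j = 0; j < m.L35; ++j) cbase[j] = c[o + j];
      for (int j = 0; j < m.L10; ++j) cbase[m.L35 + j] = c[od + j];
      for (int k = 0; k < nct; ++k) {
        int bk4 = cbase[k] * 4;
        const int koff = k * nct;
        for (int l = k + 1; l < nct; ++l) {
          score[pair_off[koff + l] + bk4 + cbase[l]] += f;
        }
      }
    }
  }
  return score;
}

// Extract the sufficient structure for a fast 1-D likelihood profile in a
// single candidate interaction: per-sequence base sums S_on / S_np and the
// (t, class) of every configuration matching the candidate.
// [[Rcpp::export]]
List cpp_dinuc_extract(List seqs, IntegerVector rbs, NumericMatrix up,
                       NumericMatrix down, IntegerVector spacers,
                       NumericVector spen, IntegerMatrix dnpos,
                       NumericVector dnde, double mu, double R, int cutoff,
                       bool use_spen, bool use_occl, bool use_rc,
                       bool use_dinuc, int ck, int cbk, int cl, int cbl) {
  ModelView m = make_view(up, down, spacers, spen, dnpos, dnde, mu, R, cutoff);
  int n = seqs.size();
  NumericVector S_on(n), S_np(n);
  std::vector<int> m_seq; std::vector<double> m_t; std::vector<int> m_on;
  std::vector<double> ts; std::vector<int> kl, offs, sidx, strands, rcbuf;
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    const int *fwd = sq.begin();
    scan_sequence(fwd, sq.size(), m, use_spen, use_occl, use_rc, use_dinuc,
                  rbs[s], ts, kl, offs, sidx, strands, rcbuf);
    long double son = 0.0L, snp = 0.0L;
    int nc = ts.size();
    for (int i = 0; i < nc; ++i) {
      double w = std::exp(log_weight(ts[i], R));
      if (kl[i] == 0) son += w; else snp += w;
      // candidate match?
      int o = offs[i], sp = m.spacers[sidx[i]];
      const int *c = strands[i] == 0 ? fwd : rcbuf.data();
      int od = o + m.L35 + sp;
      int bk = (ck < m.L35) ? c[o + ck] : c[od + (ck - m.L35)];
      int bl = (cl < m.L35) ? c[o + cl] : c[od + (cl - m.L35)];
      if (bk == cbk && bl == cbl) {
        m_seq.push_back(s); m_t.push_back(ts[i]);
        m_on.push_back(kl[i] == 0 ? 1 : 0);
      }
    }
    S_on[s] = (double)son; S_np[s] = (double)snp;
  }
  return List::create(_["S_on"] = S_on, _["S_np"] = S_np,
                      _["m_seq"] = wrap(m_seq), _["m_t"] = wrap(m_t),
                      _["m_on"] = wrap(m_on));
}

// Log-likelihood as a function of a single candidate delta, given the
// extracted structure.
// [[Rcpp::export]]
double cpp_dinuc_ll(NumericVector S_on, NumericVector S_np,
                    IntegerVector m_seq, NumericVector m_t, IntegerVector m_on,
                    double delta, double R, IntegerVector y, NumericVector wgt,
                    NumericVector a, NumericVector b) {
  int n = S_on.size(), B = a.size();
  std::vector<double> d_on(n, 0.0), d_np(n, 0.0);
  int nm = m_seq.size();
  for (int i = 0; i < nm; ++i) {
    double w0 = std::exp(log_weight(m_t[i], R));
    double w1 = std::exp(log_weight(m_t[i] + delta, R));
    if (m_on[i]) d_on[m_seq[i]] += w1 - w0; else d_np[m_seq[i]] += w1 - w0;
  }
  double ll_tot = 0.0;
  for (int s = 0; s < n; ++s) {
    double son = S_on[s] + d_on[s], snp = S_np[s] + d_np[s];
    if (son <= 0) continue;
    double x = (std::log(son) - std::log1p(snp + son)) / LN10;
    double ll, g;
    link_ll_grad(x, y[s], wgt[s], a.begin(), b.begin(), B, ll, g);
    ll_tot += ll;
  }
  return ll_tot;
}

// Prune-extract: full per-sequence weight sums plus the subset of
// configurations whose weight is non-negligible (w >= keep_frac times the
// sequence's largest weight), with their contact residues.  Interaction
// terms only matter through configurations that carry weight, so
// candidate profiles evaluated on the pruned set are exact to the
// pruning tolerance.
// [[Rcpp::export]]
List cpp_prune_extract(List seqs, IntegerVector rbs, NumericMatrix up,
                       NumericMatrix down, IntegerVector spacers,
                       NumericVector spen, IntegerMatrix dnpos,
                       NumericVector dnde, double mu, double R, int cutoff,
                       bool use_spen, bool use_occl, bool use_rc,
                       bool use_dinuc, double keep_frac) {
  ModelView m = make_view(up, down, spacers, spen, dnpos, dnde, mu, R,
                          cutoff);
  int n = seqs.size();
  int nct = m.L35 + m.L10;
  NumericVector S_on(n), S_np(n);
  std::vector<double> p_t; std::vector<int> p_on, p_seq;
  std::vector<unsigned char> p_ct;
  std::vector<double> ts; std::vector<int> kl, offs, sidx, strands, rcbuf;
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    const int *fwd = sq.begin();
    scan_sequence(fwd, sq.size(), m, use_spen, use_occl, use_rc, use_dinuc,
                  rbs[s], ts, kl, offs, sidx, strands, rcbuf);
    int nc = ts.size();
    long double son = 0.0L, snp = 0.0L;
    double tmin = R_PosInf;
    for (int i = 0; i < nc; ++i) {
      double w = std::exp(log_weight(ts[i], R));
      if (kl[i] == 0) son += w; else snp += w;
      if (ts[i] < tmin) tmin = ts[i];
    }
    S_on[s] = (double)son; S_np[s] = (double)snp;
    double wmax = std::exp(log_weight(tmin, R));
    double thresh = wmax * keep_frac;
    for (int i = 0; i < nc; ++i) {
      if (std::exp(log_weight(ts[i], R)) < thresh) continue;
      p_t.push_back(ts[i]);
      p_on.push_back(kl[i] == 0 ? 1 : 0);
      p_seq.push_back(s);
      int o = offs[i], sp = m.spacers[sidx[i]];
      const int *c = strands[i] == 0 ? fwd : rcbuf.data();
      int od = o + m.L35 + sp;
      for (int j = 0; j < m.L35; ++j)
        p_ct.push_back((unsigned char)c[o + j]);
      for (int j = 0; j < m.L10; ++j)
        p_ct.push_back((unsigned char)c[od + j]);
    }
  }
  int np = p_t.size();
  RawMatrix contacts(nct, np);  // column-major: one column per config
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < nct; ++j)
      contacts(j, i) = p_ct[(size_t)i * nct + j];
  return List::create(_["S_on"] = S_on, _["S_np"] = S_np,
                      _["t"] = wrap(p_t), _["on"] = wrap(p_on),
                      _["seq"] = wrap(p_seq), _["contacts"] = contacts);
}

// Exact likelihood-improvement profiles for every candidate interaction
// over a grid of interaction energies, using a pruned extract.  Returns
// an (n_candidates x n_grid) matrix of LL(delta) - LL(0), with
// candidates in the canonical order (position pairs k<l, then
// base_i*4+base_j).
// [[Rcpp::export]]
NumericMatrix cpp_stage1_grid(NumericVector S_on, NumericVector S_np,
                              NumericVector p_t, IntegerVector p_on,
                              IntegerVector p_seq, RawMatrix contacts,
                              IntegerVector y, NumericVector wgt,
                              NumericVector a, NumericVector b, double R,
                              NumericVector grid) {
  int n = S_on.size(), B = a.size(), np = p_t.size();
  int nct = contacts.nrow();
  int ng = grid.size();
  // baseline per-sequence log-likelihood
  std::vector<double> ll0(n, 0.0);
  for (int s = 0; s < n; ++s) {
    if (S_on[s] <= 0) continue;
    double x = (std::log(S_on[s]) - std::log1p(S_np[s] + S_on[s])) / LN10;
    double ll, g;
    link_ll_grad(x, y[s], wgt[s], a.begin(), b.begin(), B, ll, g);
    ll0[s] = ll;
  }
  // precompute per-config base weights
  std::vector<double> w0(np);
  for (int i = 0; i < np; ++i) w0[i] = std::exp(log_weight(p_t[i], R));
  int n_pair = nct * (nct - 1) / 2;
  NumericMatrix out(n_pair * 16, ng);
  std::vector<int> matched; matched.reserve(np / 8);
  std::vector<double> d_on(n), d_np(n);
  std::vector<int> touched; touched.reserve(n);
  int ci = 0;
  for (int k = 0; k < nct; ++k) {
    for (int l = k + 1; l < nct; ++l) {
      for (int bk = 0; bk < 4; ++bk) {
        for (int bl = 0; bl < 4; ++bl, ++ci) {
          matched.clear();
          const Rbyte *cc = &contacts(0, 0);
          for (int i = 0; i < np; ++i) {
            const Rbyte *col = cc + (size_t)i * nct;
            if (col[k] == bk && col[l] == bl) matched.push_back(i);
          }
          if (matched.empty()) continue;
          for (int g2 = 0; g2 < ng; ++g2) {
            double delta = grid[g2];
            double fac = std::exp(-delta);  // w(t+delta)/w(t) when R=0
            touched.clear();
            for (size_t mi = 0; mi < matched.size(); ++mi) {
              int i = matched[mi];
              int s = p_seq[i];
              double w1 = (R == 0.0) ? w0[i] * fac
                          : std::exp(log_weight(p_t[i] + delta, R));
              double dw = w1 - w0[i];
              if (d_on[s] == 0.0 && d_np[s] == 0.0) touched.push_back(s);
              if (p_on[i]) d_on[s] += dw; else d_np[s] += dw;
            }
            double dll = 0.0;
            for (size_t ti = 0; ti < touched.size(); ++ti) {
              int s = touched[ti];
              double son = S_on[s] + d_on[s], snp = S_np[s] + d_np[s];
              d_on[s] = 0.0; d_np[s] = 0.0;
              if (son <= 0) { dll -= ll0[s]; continue; }
              double x = (std::log(son) - std::log1p(snp + son)) / LN10;
              double ll, g;
              link_ll_grad(x, y[s], wgt[s], a.begin(), b.begin(), B, ll, g);
              dll += ll - ll0[s];
            }
            out(ci, g2) = dll;
          }
        }
      }
    }
  }
  return out;
}

// Pre-extract the structure needed for fast joint fits of a candidate
// subset's interaction energies: per-configuration base energies (t0 =
// E - mu, without any candidate contribution), classes, per-sequence
// config ranges, and the (config, candidate) match pairs.
// [[Rcpp::export]]
List cpp_subset_extract(List seqs, IntegerVector rbs, NumericMatrix up,
                        NumericMatrix down, IntegerVector spacers,
                        NumericVector spen, IntegerMatrix dnpos,
                        NumericVector dnde, double mu, double R, int cutoff,
                        bool use_spen, bool use_occl, bool use_rc,
                        bool use_dinuc, IntegerMatrix cand) {
  ModelView m = make_view(up, down, spacers, spen, dnpos, dnde, mu, R,
                          cutoff);
  int n = seqs.size(), nc_cand = cand.nrow();
  std::vector<double> t0; std::vector<int> klv, seq_ptr(n + 1, 0);
  std::vector<int> match_cfg, match_cand;
  std::vector<double> ts; std::vector<int> kl, offs, sidx, strands, rcbuf;
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    const int *fwd = sq.begin();
    scan_sequence(fwd, sq.size(), m, use_spen, use_occl, use_rc, use_dinuc,
                  rbs[s], ts, kl, offs, sidx, strands, rcbuf);
    int base = t0.size();
    int nc = ts.size();
    for (int i = 0; i < nc; ++i) {
      t0.push_back(ts[i]); klv.push_back(kl[i]);
      int o = offs[i], sp = m.spacers[sidx[i]];
      const int *c = strands[i] == 0 ? fwd : rcbuf.data();
      int od = o + m.L35 + sp;
      for (int k = 0; k < nc_cand; ++k) {
        int pi = cand(k, 0), bi = cand(k, 1), pj = cand(k, 2),
            bj = cand(k, 3);
        int posi = (pi < m.L35) ? o + pi : od + (pi - m.L35);
        int posj = (pj < m.L35) ? o + pj : od + (pj - m.L35);
        if (c[posi] == bi && c[posj] == bj) {
          match_cfg.push_back(base + i);
          match_cand.push_back(k);
        }
      }
    }
    seq_ptr[s + 1] = t0.size();
  }
  return List::create(_["t0"] = wrap(t0), _["klass"] = wrap(klv),
                      _["seq_ptr"] = wrap(seq_ptr),
                      _["match_cfg"] = wrap(match_cfg),
                      _["match_cand"] = wrap(match_cand));
}

// Log-likelihood and gradient over the candidate deltas, given an
// extract from cpp_subset_extract.
// [[Rcpp::export]]
List cpp_subset_llgrad(NumericVector t0, IntegerVector klass,
                       IntegerVector seq_ptr, IntegerVector match_cfg,
                       IntegerVector match_cand, NumericVector deltas,
                       double R, IntegerVector y, NumericVector wgt,
                       NumericVector a, NumericVector b, bool want_grad) {
  int n = seq_ptr.size() - 1, B = a.size(), ncfg = t0.size();
  int nd = deltas.size(), nm = match_cfg.size();
  std::vector<double> dt(ncfg, 0.0);
  for (int i = 0; i < nm; ++i) dt[match_cfg[i]] += deltas[match_cand[i]];
  std::vector<double> dxdE(ncfg, 0.0);
  NumericVector g_delta(nd);
  double ll_tot = 0.0;
  std::vector<double> lw;
  for (int s = 0; s < n; ++s) {
    int lo = seq_ptr[s], hi = seq_ptr[s + 1];
    double max_on = R_NegInf, max_all = 0.0;
    lw.assign(hi - lo, 0.0);
    for (int i = lo; i < hi; ++i) {
      lw[i - lo] = log_weight(t0[i] + dt[i], R);
      if (klass[i] == 0 && lw[i - lo] > max_on) max_on = lw[i - lo];
      if (lw[i - lo] > max_all) max_all = lw[i - lo];
    }
    if (max_on == R_NegInf) continue;
    double s_on = 0.0, s_all = std::exp(0.0 - max_all);
    for (int i = lo; i < hi; ++i) {
      if (klass[i] == 0) s_on += std::exp(lw[i - lo] - max_on);
      s_all += std::exp(lw[i - lo] - max_all);
    }
    double logSon = max_on + std::log(s_on);
    double logD = max_all + std::log(s_all);
    double x = (logSon - logD) / LN10;
    double ll, g;
    link_ll_grad(x, y[s], wgt[s], a.begin(), b.begin(), B, ll, g);
    ll_tot += ll;
    if (!want_grad) continue;
    for (int i = lo; i < hi; ++i) {
      double lwi = lw[i - lo];
      double q = std::exp(lwi - logD);
      double omRw = std::exp(t0[i] + dt[i] + lwi);
      double d;
      if (klass[i] == 0) {
        double r = std::exp(lwi - logSon);
        d = -(r - q) * omRw / LN10;
      } else {
        d = q * omRw / LN10;
      }
      dxdE[i] = g * d;
    }
  }
  if (want_grad)
    for (int i = 0; i < nm; ++i) g_delta[match_cand[i]] += dxdE[match_cfg[i]];
  return List::create(_["ll"] = ll_tot, _["grad_delta"] = g_delta);
}

// Per-position free binding energy over a genome: at each position p the
// "-10 end" of a configuration, F(p) = -log sum_spacers exp(-E(p, spacer)).
// Positions where no full configuration fits are NA (linear mode).
// [[Rcpp::export]]
NumericVector cpp_energy_track(IntegerVector codes, NumericMatrix up,
                               NumericMatrix down, IntegerVector spacers,
                               NumericVector spen, IntegerMatrix dnpos,
                               NumericVector dnde, bool use_dinuc,
                               bool circular) {
  ModelView m = make_view(up, down, spacers, spen, dnpos, dnde, 0.0, 0.0, 0);
  int L = codes.size();
  NumericVector out(L, NA_REAL);
  std::vector<int> c;
  const int *cp;
  int shift = 0;
  if (circular) {
    // unroll the wrap: prepend the last (maxwidth-1) bases
    int wmax = m.L35 + m.spacers[m.n_sp - 1] + m.L10;
    c.resize(L + wmax - 1);
    for (int i = 0; i < wmax - 1; ++i) c[i] = codes[L - (wmax - 1) + i];
    for (int i = 0; i < L; ++i) c[wmax - 1 + i] = codes[i];
    cp = c.data(); shift = wmax - 1;
  } else {
    cp = codes.begin();
  }
  std::vector<double> negE(m.n_sp);
  for (int p = 0; p < L; ++p) {
    int pp = p + shift;
    double mx = R_NegInf;
    int nv = 0;
    for (int si = 0; si < m.n_sp; ++si) {
      int w = m.L35 + m.spacers[si] + m.L10;
      int o = pp - (w - 1);
      if (o < 0) continue;
      double E = config_energy(cp, o, si, m, true, use_dinuc);
      negE[nv] = -E;
      if (-E > mx) mx = -E;
      ++nv;
    }
    if (nv == 0) continue;
    double s = 0.0;
    for (int i = 0; i < nv; ++i) s += std::exp(negE[i] - mx);
    out[p] = -(mx + std::log(s));
  }
  return out;
}
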