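#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <functional>
using namespace Rcpp;

static const double INF = 1e9;

// pair codes: 0 none, 1 AU, 2 UA, 3 CG, 4 GC, 5 GU, 6 UG
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'U': case 'T': return 3; default: return -1;
  }
}
static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 1) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

struct EnergyPar {
  double stack[7][7];
  std::vector<double> hairpin, bulge, internal_;
  double lxc, ninio_m, ninio_max;
  double ml_close, ml_branch, ml_unpaired;
  int min_hairpin, max_interior;

  double hairpinE(int n) const {
    if (n < min_hairpin) return INF;
    if (n < (int)hairpin.size()) return hairpin[n];
    int nmax = hairpin.size() - 1;
    return hairpin[nmax] + lxc * std::log((double)n / nmax);
  }
  double bulgeE(int n) const {
    if (n < (int)bulge.size()) return bulge[n];
    int nmax = bulge.size() - 1;
    return bulge[nmax] + lxc * std::log((double)n / nmax);
  }
  double internalE(int n) const {
    if (n < (int)internal_.size()) return internal_[n];
    int nmax = internal_.size() - 1;
    return internal_[nmax] + lxc * std::log((double)n / nmax);
  }
  // two-sided loop between stacked pairs p1 (outer) and p2 (inner),
  // n1/n2 unpaired on each side
  double interiorE(int p1, int p2, int n1, int n2) const {
    if (n1 == 0 && n2 == 0) return stack[p1][p2];
    int ntot = n1 + n2;
    if (ntot > max_interior) return INF;
    if (n1 == 0 || n2 == 0) {
      double e = bulgeE(ntot);
      if (ntot == 1) e += stack[p1][p2];  // single bulge keeps the stack
      return e;
    }
    double asym = ninio_m * std::abs(n1 - n2);
    if (asym > ninio_max) asym = ninio_max;
    return internalE(ntot) + asym;
  }
};

static EnergyPar parse_par(List par) {
  EnergyPar P;
  NumericMatrix st = par["stack"];
  for (int i = 0; i < 7; i++)
    for (int j = 0; j < 7; j++) P.stack[i][j] = INF;
  for (int i = 1; i <= 6; i++)
    for (int j = 1; j <= 6; j++) P.stack[i][j] = st(i - 1, j - 1);
  NumericVector h = par["hairpin"], b = par["bulge"], in = par["internal"];
  P.hairpin.assign(h.size() + 1, INF);
  for (int i = 0; i < h.size(); i++) P.hairpin[i + 1] = h[i];
  P.bulge.assign(b.size() + 1, INF);
  for (int i = 0; i < b.size(); i++) P.bulge[i + 1] = b[i];
  P.internal_.assign(in.size() + 1, INF);
  for (int i = 0; i < in.size(); i++) P.internal_[i + 1] = in[i];
  P.lxc = as<double>(par["lxc"]);
  P.ninio_m = as<double>(par["ninio_m"]);
  P.ninio_max = as<double>(par["ninio_max"]);
  P.ml_close = as<double>(par["ml_close"]);
  P.ml_branch = as<double>(par["ml_branch"]);
  P.ml_unpaired = as<double>(par["ml_unpaired"]);
  P.min_hairpin = as<int>(par["min_hairpin"]);
  P.max_interior = as<int>(par["max_interior"]);
  return P;
}

// Zuker-style MFE fold, no pseudoknots. Returns dot-bracket + energy.
// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, List par) {
  EnergyPar P = parse_par(par);
  int n = seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; i++) s[i] = base_code(seq[i]);

  // V[i][j]: MFE given i,j paired; M[i][j]: multiloop segment, >=1 branch
  std::vector<std::vector<double>> V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double>> M(n, std::vector<double>(n, INF));
  auto canpair = [&](int i, int j) {
    return s[i] >= 0 && s[j] >= 0 && pair_code(s[i], s[j]) != 0;
  };

  for (int d = P.min_hairpin + 1; d < n; d++) {
    for (int i = 0; i + d < n; i++) {
      int j = i + d;
      // V
      if (canpair(i, j)) {
        int pij = pair_code(s[i], s[j]);
        double best = P.hairpinE(j - i - 1);
        for (int k = i + 1; k < j; k++) {
          if (k - i - 1 > P.max_interior) break;
          for (int l = j - 1; l > k; l--) {
            if ((k - i - 1) + (j - l - 1) > P.max_interior) break;
            if (V[k][l] >= INF) continue;
            double e = P.interiorE(pij, pair_code(s[k], s[l]),
                                   k - i - 1, j - l - 1);
            if (e < INF && V[k][l] + e < best) best = V[k][l] + e;
          }
        }
        // multiloop closed by (i,j)
        for (int k = i + 1; k < j - 1; k++) {
          if (M[i + 1][k] < INF && M[k + 1][j - 1] < INF) {
            double e = M[i + 1][k] + M[k + 1][j - 1] + P.ml_close + P.ml_branch;
            if (e < best) best = e;
          }
        }
        V[i][j] = best;
      }
      // M
      double m = INF;
      if (j > i && M[i][j - 1] < INF) m = std::min(m, M[i][j - 1] + P.ml_unpaired);
      if (j > i && M[i + 1][j] < INF) m = std::min(m, M[i + 1][j] + P.ml_unpaired);
      if (V[i][j] < INF) m = std::min(m, V[i][j] + P.ml_branch);
      for (int k = i + 1; k <= j; k++)
        if (M[i][k - 1] < INF && V[k][j] < INF)
          m = std::min(m, M[i][k - 1] + V[k][j] + P.ml_branch);
      M[i][j] = m;
    }
  }
  // small j-i for M (single unpaired runs can't branch -> stays INF); fill V/M
  // above loop starts at d=min_hairpin+1 so short spans remain INF, fine.

  // exterior
  std::vector<double> W(n + 1, 0.0);
  for (int j = 1; j <= n; j++) {
    W[j] = W[j - 1];
    for (int i = 1; i <= j; i++)
      if (V[i - 1][j - 1] < INF && W[i - 1] + V[i - 1][j - 1] < W[j])
        W[j] = W[i - 1] + V[i - 1][j - 1];
  }
  double mfe = W[n];

  // traceback
  std::string db(n, '.');
  const double EPS = 1e-7;
  std::vector<std::pair<int, int>> stackW, stackV, stackM;
  { // exterior trace
    int j = n;
    while (j > 0) {
      if (std::abs(W[j] - W[j - 1]) < EPS) { j--; continue; }
      bool found = false;
      for (int i = 1; i <= j; i++) {
        if (V[i - 1][j - 1] < INF &&
            std::abs(W[j] - (W[i - 1] + V[i - 1][j - 1])) < EPS) {
          stackV.push_back({i - 1, j - 1});
          j = i - 1; found = true; break;
        }
      }
      if (!found) j--;  // defensive
    }
  }
  std::function<void(int, int)> traceV, traceM;
  traceV = [&](int i, int j) {
    db[i] = '('; db[j] = ')';
    int pij = pair_code(s[i], s[j]);
    if (std::abs(V[i][j] - P.hairpinE(j - i - 1)) < EPS) return;
    for (int k = i + 1; k < j; k++) {
      if (k - i - 1 > P.max_interior) break;
      for (int l = j - 1; l > k; l--) {
        if ((k - i - 1) + (j - l - 1) > P.max_interior) break;
        if (V[k][l] >= INF) continue;
        double e = P.interiorE(pij, pair_code(s[k], s[l]), k - i - 1, j - l - 1);
        if (e < INF && std::abs(V[i][j] - (V[k][l] + e)) < EPS) {
          traceV(k, l); return;
        }
      }
    }
    for (int k = i + 1; k < j - 1; k++) {
      if (M[i + 1][k] < INF && M[k + 1][j - 1] < INF &&
          std::abs(V[i][j] - (M[i + 1][k] + M[k + 1][j - 1] +
                              P.ml_close + P.ml_branch)) < EPS) {
        traceM(i + 1, k); traceM(k + 1, j - 1); return;
      }
    }
  };
  traceM = [&](int i, int j) {
    while (true) {
      if (j > i && M[i][j - 1] < INF &&
          std::abs(M[i][j] - (M[i][j - 1] + P.ml_unpaired)) < EPS) { j--; continue; }
      if (j > i && M[i + 1][j] < INF &&
          std::abs(M[i][j] - (M[i + 1][j] + P.ml_unpaired)) < EPS) { i++; continue; }
      break;
    }
    if (V[i][j] < INF && std::abs(M[i][j] - (V[i][j] + P.ml_branch)) < EPS) {
      traceV(i, j); return;
    }
    for (int k = i + 1; k <= j; k++) {
      if (M[i][k - 1] < INF && V[k][j] < INF &&
          std::abs(M[i][j] - (M[i][k - 1] + V[k][j] + P.ml_branch)) < EPS) {
        traceV(k, j); traceM(i, k - 1); return;
      }
    }
  };
  while (!stackV.empty()) {
    auto pr = stackV.back(); stackV.pop_back();
    traceV(pr.first, pr.second);
  }

  return List::create(_["structure"] = db, _["mfe"] = mfe);
}

// Intermolecular duplex MFE: x (5'->3') vs y (5'->3'), antiparallel pairing,
// no intramolecular structure. 0 = no pairing; single pair costs 0.
// [[Rcpp::export(name = ".duplex_energy_cpp")]]
double duplex_energy_cpp(std::string x, std::string y, List par, int max_loop) {
  EnergyPar P = parse_par(par);
  int m = x.size(), n = y.size();
  std::vector<int> sx(m), sy(n);
  for (int i = 0; i < m; i++) sx[i] = base_code(x[i]);
  for (int j = 0; j < n; j++) sy[j] = base_code(y[j]);
  // E[i][j]: best energy of a duplex whose last (3'-most on x) pair is (i,j)
  std::vector<std::vector<double>> E(m, std::vector<double>(n, INF));
  double best = 0.0;
  for (int i = 0; i < m; i++) {
    for (int j = n - 1; j >= 0; j--) {
      if (sx[i] < 0 || sy[j] < 0) continue;
      int pij = pair_code(sx[i], sy[j]);
      if (pij == 0) continue;
      double e = 0.0;  // duplex opened here
      for (int pi = i - 1; pi >= 0 && i - pi - 1 <= max_loop; pi--) {
        for (int pj = j + 1; pj < n && pj - j - 1 <= max_loop; pj++) {
          if (E[pi][pj] >= INF) continue;
          int ppr = pair_code(sx[pi], sy[pj]);
          double le = P.interiorE(ppr, pij, i - pi - 1, pj - j - 1);
          if (le < INF && E[pi][pj] + le < e) e = E[pi][pj] + le;
        }
      }
      E[i][j] = e;
      if (e < best) best = e;
    }
  }
  return best;
}

// 3'-adapter trimming: remove the longest read suffix that matches a prefix
// of the adapter with overlap >= min_overlap and mismatch fraction <= rate.
// [[Rcpp::export(name = ".trim_adapter_cpp")]]
IntegerVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                               int min_overlap, double max_mismatch_rate) {
  int n = reads.size(), alen = adapter.size();
  IntegerVector keep(n);  // kept insert length per read
  for (int r = 0; r < n; r++) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    int L = LENGTH(STRING_ELT(reads, r));
    int cut = L;
    int maxov = std::min(L, alen);
    for (int k = maxov; k >= min_overlap; k--) {  // longest suffix first
      int st = L - k, mm = 0, allow = (int)std::floor(max_mismatch_rate * k);
      for (int t = 0; t < k; t++) {
        char a = rd[st + t], b = adapter[t];
        if (a == 'T') a = 'U';
        if (b == 'T') b = 'U';
        if (a != b && ++mm > allow) break;
      }
      if (mm <= allow) { cut = st; break; }
    }
    keep[r] = cut;
  }
  return keep;
}
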