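// Event-driven spatial kinetic Monte Carlo engine for the chambered synapse
// model: chamber-local reaction channels, diffusive hops, microcluster
// formation hops (logistic acceptance on a local pVav1 potential),
// saturable centripetal cluster hops, rim influx, periodic homogenization of
// cytosolic species, and excluded-volume caps.
//
// Exact sampling: waiting times are exponential in the total propensity and
// events are chosen proportionally; state-dependent acceptance (formation
// sigmoid, hop direction, capacity) is applied by thinning against constant
// upper bounds, which leaves the sampled process exact.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

namespace {

struct SumTree {
  int P;                      // leaf offset (power of two)
  std::vector<double> t;
  void init(int n) {
    P = 1;
    while (P < n) P <<= 1;
    t.assign(2 * P, 0.0);
  }
  void set(int i, double v) {
    i += P;
    t[i] = v;
    for (i >>= 1; i >= 1; i >>= 1) t[i] = t[2 * i] + t[2 * i + 1];
  }
  double total() const { return t[1]; }
  // find leaf with cumulative sum exceeding u (0 <= u < total)
  int sample(double u) const {
    int i = 1;
    while (i < P) {
      i <<= 1;
      if (u >= t[i]) { u -= t[i]; ++i; }
    }
    return i - P;
  }
};

struct Engine {
  // geometry
  int nx, ny, NC;
  double l0, R;
  // state
  std::vector<int> cnt;        // NC * NS
  std::vector<int> rimN, rimL, rimC0;
  std::vector<int> rimDest;    // box chamber each rim chamber feeds
  std::vector<int> flag;       // immobile microcluster chamber
  int NS, NCH, NR;
  // channels
  std::vector<double> chRate;
  std::vector<int> reac1, reac2;               // species indices, -1 if none
  std::vector<std::vector<int> > prodIdx;      // products (with multiplicity)
  // species metadata
  std::vector<double> diffRate;                // per-direction hop rate
  std::vector<int> isCap, nkM, pvM, isClust, isHomog, frozenFlag;
  std::vector<int> diffSp, clustSp;            // index lists
  // spatial params
  double baseForm, kcm, K, w, beta, kInflux, tauH;
  int Nthres, Nmax, clustering, coclust, sConst1;
  double rimBindRate, rimKoff;
  // caches
  std::vector<int> memTot, nkTot, pvLoc;
  long long PV;
  SumTree tree;                // NC box leaves + NR rim leaves
  std::vector<double> scratch;
  // rng
  std::mt19937_64 rng;
  double t;
  // counters
  long long nReact, nDiff, nForm, nClustHop, nInflux, nReject, nRimReact;

  double runif() {
    return (rng() >> 11) * (1.0 / 9007199254740992.0);  // [0,1)
  }

  int at(int c, int s) const { return cnt[c + (long)NC * s]; }
  void bump(int c, int s, int d) {
    cnt[c + (long)NC * s] += d;
    memTot[c] += d * isCap[s];
    nkTot[c] += d * nkM[s];
    int dp = d * pvM[s];
    pvLoc[c] += dp;
    PV += dp;
  }

  int nb(int c, int dir) const {
    // periodic neighbor; dir: 0 left(-x) 1 right(+x) 2 down(-y) 3 up(+y)
    int i = c % nx, j = c / nx;
    switch (dir) {
      case 0: i = (i + nx - 1) % nx; break;
      case 1: i = (i + 1) % nx; break;
      case 2: j = (j + ny - 1) % ny; break;
      default: j = (j + 1) % ny; break;
    }
    return i + nx * j;
  }
  // non-periodic neighbor: -1 outside the box
  int nbHard(int c, int dir) const {
    int i = c % nx, j = c / nx;
    switch (dir) {
      case 0: --i; break;
      case 1: ++i; break;
      case 2: --j; break;
      default: ++j; break;
    }
    if (i < 0 || i >= nx || j < 0 || j >= ny) return -1;
    return i + nx * j;
  }

  double potential(int c) const {
    double x = pvLoc[c];
    double e = -x * x;
    for (int d = 0; d < 4; ++d) {
      double xn = pvLoc[nb(c, d)];
      double en = -xn * xn;
      if (en < e) e = en;
    }
    return e;
  }

  // total propensity of a box chamber; if fill, also writes per-event terms
  double chamberProp(int c, double *fill) {
    double a = 0.0;
    int base = 0;
    for (int k = 0; k < NCH; ++k) {
      double p = chRate[k];
      if (p > 0.0) {
        p *= at(c, reac1[k]);
        if (reac2[k] >= 0) p *= at(c, reac2[k]);
      }
      if (fill) fill[base + k] = p;
      a += p;
    }
    base += NCH;
    int nd = (int)diffSp.size();
    // free monomers diffuse everywhere except species pinned in flagged
    // (immobile microcluster) chambers; complexes in flagged chambers emit
    // no formation/cluster hops
    for (int q = 0; q < nd; ++q) {
      int s = diffSp[q];
      double p = (flag[c] && frozenFlag[s]) ? 0.0
                 : 4.0 * diffRate[s] * at(c, s);
      if (fill) fill[base + q] = p;
      a += p;
    }
    base += nd;
    int ncl = (int)clustSp.size();
    if (clustering) {
      for (int q = 0; q < ncl; ++q) {
        double p = flag[c] ? 0.0 : 4.0 * baseForm * at(c, clustSp[q]);
        if (fill) fill[base + q] = p;
        a += p;
      }
      base += ncl;
      for (int q = 0; q < ncl; ++q) {
        double p = (!flag[c] && at(c, clustSp[q]) > 0) ? kcm : 0.0;
        if (fill) fill[base + q] = p;
        a += p;
      }
    }
    return a;
  }

  void refreshChamber(int c) { tree.set(c, chamberProp(c, nullptr)); }

  double rimProp(int r) const {
    return rimBindRate * rimN[r] * rimL[r] + (rimKoff + kInflux) * rimC0[r];
  }
  void refreshRim(int r) { tree.set(NC + r, rimProp(r)); }

  void rebuildAll() {
    memTot.assign(NC, 0);
    nkTot.assign(NC, 0);
    pvLoc.assign(NC, 0);
    PV = 0;
    for (int c = 0; c < NC; ++c)
      for (int s = 0; s < NS; ++s) {
        int n = at(c, s);
        memTot[c] += n * isCap[s];
        nkTot[c] += n * nkM[s];
        pvLoc[c] += n * pvM[s];
        PV += (long long)n * pvM[s];
      }
    for (int c = 0; c < NC; ++c) refreshChamber(c);
    for (int r = 0; r < NR; ++r) refreshRim(r);
  }

  bool capacityOK(int dest, int mem, int nk) const {
    return memTot[dest] + mem <= Nthres && nkTot[dest] + nk <= Nmax;
  }

  int largestClustSpecies(int c) const {
    int best = -1, bn = 0;
    for (size_t q = 0; q < clustSp.size(); ++q) {
      int n = at(c, clustSp[q]);
      if (n > bn) { bn = n; best = clustSp[q]; }
    }
    return best;
  }

  void moveMolecules(int c, int dest, int s, int n) {
    bump(c, s, -n);
    bump(dest, s, n);
  }

  // carried membrane-proximal Vav1/pVav1 for co-clustering hops
  int sVav1, sPVav1;
  void execHop(int c, int dest, int s, int n, bool carry) {
    int carryV = 0, carryP = 0;
    if (carry && coclust && s == largestClustSpecies(c)) {
      carryV = at(c, sVav1);
      carryP = at(c, sPVav1);
    }
    int mem = n * isCap[s] + carryV * isCap[sVav1] + carryP * isCap[sPVav1];
    int nk = n * nkM[s];
    if (!capacityOK(dest, mem, nk)) { ++nReject; return; }
    moveMolecules(c, dest, s, n);
    if (carryV) moveMolecules(c, dest, sVav1, carryV);
    if (carryP) moveMolecules(c, dest, sPVav1, carryP);
    refreshChamber(c);
    refreshChamber(dest);
  }

  void executeChamberEvent(int c) {
    double a = chamberProp(c, scratch.data());
    double u = runif() * a;
    int nd = (int)diffSp.size(), ncl = (int)clustSp.size();
    int nev = NCH + nd + (clustering ? 2 * ncl : 0);
    int k = 0;
    for (; k < nev - 1; ++k) {
      if (u < scratch[k]) break;
      u -= scratch[k];
    }
    if (k < NCH) {
      // reaction
      bump(c, reac1[k], -1);
      if (reac2[k] >= 0) bump(c, reac2[k], -1);
      for (size_t q = 0; q < prodIdx[k].size(); ++q) bump(c, prodIdx[k][q], 1);
      refreshChamber(c);
      ++nReact;
      return;
    }
    k -= NCH;
    if (k < nd) {
      // single-molecule diffusive hop, periodic
      int s = diffSp[k];
      int dir = (int)(runif() * 4.0);
      if (dir > 3) dir = 3;
      int dest = nb(c, dir);
      if (dest == c) { ++nReject; return; }
      int mem = isCap[s], nk = nkM[s];
      if (!capacityOK(dest, mem, nk)) { ++nReject; return; }
      moveMolecules(c, dest, s, 1);
      refreshChamber(c);
      refreshChamber(dest);
      ++nDiff;
      return;
    }
    k -= nd;
    if (k < ncl) {
      // microcluster-formation hop: one complex, sigmoid acceptance
      int s = clustSp[k];
      int dir = (int)(runif() * 4.0);
      if (dir > 3) dir = 3;
      int dest = nbHard(c, dir);
      if (dest < 0) { ++nReject; return; }
      double Ei = potential(c), Ej = potential(dest);
      double d = beta * (Ei - Ej);
      double p = (d > 0) ? 1.0 / (1.0 + std::exp(-d))
                         : std::exp(d) / (1.0 + std::exp(d));
      if (runif() >= p) { ++nReject; return; }
      execHop(c, dest, s, 1, true);
      ++nForm;
      return;
    }
    k -= ncl;
    {
      // centripetal/random cluster hop: all copies of one complex species
      int s = clustSp[k];
      int n = at(c, s);
      if (n <= 0) { ++nReject; return; }
      double x = ((c % nx) + 0.5) * l0, y = ((c / nx) + 0.5) * l0;
      double sfac = sConst1 ? 1.0 : (double)PV / (K + (double)PV);
      double gx = sfac * (x / R - 1.0), gy = sfac * (y / R - 1.0);
      double pdir[4];
      pdir[0] = 0.25 * (1.0 + gx) * w + 0.25 * (1.0 - w);  // left
      pdir[1] = 0.25 * (1.0 - gx) * w + 0.25 * (1.0 - w);  // right
      pdir[2] = 0.25 * (1.0 + gy) * w + 0.25 * (1.0 - w);  // down
      pdir[3] = 0.25 * (1.0 - gy) * w + 0.25 * (1.0 - w);  // up
      double u2 = runif();
      int dir = 0;
      for (; dir < 3; ++dir) {
        if (u2 < pdir[dir]) break;
        u2 -= pdir[dir];
      }
      int dest = nbHard(c, dir);
      if (dest < 0) { ++nReject; return; }
      execHop(c, dest, s, n, true);
      ++nClustHop;
    }
  }

  void executeRimEvent(int r) {
    double aBind = rimBindRate * rimN[r] * rimL[r];
    double aUnbind = rimKoff * rimC0[r];
    double u = runif() * (aBind + aUnbind + kInflux * rimC0[r]);
    if (u < aBind) {
      --rimN[r]; --rimL[r]; ++rimC0[r];
      ++nRimReact;
    } else if (u < aBind + aUnbind) {
      ++rimN[r]; ++rimL[r]; --rimC0[r];
      ++nRimReact;
    } else {
      // influx: a rim complex hops into its adjacent box chamber
      int dest = rimDest[r];
      int sC0 = clustSp.empty() ? -1 : clustSp[0];
      if (sC0 < 0 || !capacityOK(dest, isCap[sC0], nkM[sC0])) {
        ++nReject;
        return;
      }
      --rimC0[r];
      bump(dest, sC0, 1);
      refreshChamber(dest);
      ++nInflux;
    }
    refreshRim(r);
  }

  void homogenize() {
    for (int s = 0; s < NS; ++s) {
      if (!isHomog[s]) continue;
      long long tot = 0;
      for (int c = 0; c < NC; ++c) tot += at(c, s);
      int base = (int)(tot / NC), rem = (int)(tot % NC);
      for (int c = 0; c < NC; ++c) cnt[c + (long)NC * s] = base;
      for (int q = 0; q < rem; ++q) {
        int c = (int)(runif() * NC);
        if (c >= NC) c = NC - 1;
        ++cnt[c + (long)NC * s];
      }
    }
    rebuildAll();
  }
};

}  // namespace

// [[Rcpp::export(name = ".kmc_run")]]
List kmc_run(IntegerVector counts, int nx, int ny,
             IntegerVector rimN, IntegerVector rimL, IntegerVector rimC0,
             IntegerVector rimDest, IntegerVector flags,
             NumericVector chanRate, IntegerVector chanReac1,
             IntegerVector chanReac2, List chanProds,
             NumericVector diffRate, IntegerVector isCap,
             IntegerVector nkMoiety, IntegerVector pvMoiety,
             IntegerVector clustSpecies, IntegerVector homogSpecies,
             IntegerVector frozenFlagged,
             List par, double tEnd, NumericVector snapTimes,
             int seed, bool keepSnapshots) {
  Engine E;
  E.nx = nx; E.ny = ny; E.NC = nx * ny;
  E.NS = (int)diffRate.size();
  E.NCH = (int)chanRate.size();
  E.NR = (int)rimN.size();
  E.l0 = as<double>(par["l0"]);
  E.R = as<double>(par["R"]);
  E.cnt.assign(counts.begin(), counts.end());
  E.rimN.assign(rimN.begin(), rimN.end());
  E.rimL.assign(rimL.begin(), rimL.end());
  E.rimC0.assign(rimC0.begin(), rimC0.end());
  E.rimDest.assign(rimDest.begin(), rimDest.end());
  E.flag.assign(flags.begin(), flags.end());
  E.chRate.assign(chanRate.begin(), chanRate.end());
  E.reac1.assign(chanReac1.begin(), chanReac1.end());
  E.reac2.assign(chanReac2.begin(), chanReac2.end());
  E.prodIdx.resize(E.NCH);
  for (int k = 0; k < E.NCH; ++k) {
    IntegerVector p = chanProds[k];
    E.prodIdx[k].assign(p.begin(), p.end());
  }
  E.diffRate.assign(diffRate.begin(), diffRate.end());
  E.isCap.assign(isCap.begin(), isCap.end());
  E.nkM.assign(nkMoiety.begin(), nkMoiety.end());
  E.pvM.assign(pvMoiety.begin(), pvMoiety.end());
  E.isClust.assign(E.NS, 0);
  E.clustSp.assign(clustSpecies.begin(), clustSpecies.end());
  for (size_t q = 0; q < E.clustSp.size(); ++q) E.isClust[E.clustSp[q]] = 1;
  E.isHomog.assign(E.NS, 0);
  for (int q = 0; q < homogSpecies.size(); ++q) E.isHomog[homogSpecies[q]] = 1;
  E.frozenFlag.assign(frozenFlagged.begin(), frozenFlagged.end());
  E.diffSp.clear();
  for (int s = 0; s < E.NS; ++s)
    if (E.diffRate[s] > 0) E.diffSp.push_back(s);
  // bookkeeping deltas are recomputed from stoichiometry inside bump()

  E.baseForm = as<double>(par["base_formation_rate"]);
  E.kcm = as<double>(par["k_cluster_move"]);
  E.K = as<double>(par["K"]);
  E.w = as<double>(par["w"]);
  E.beta = as<double>(par["beta"]);
  E.kInflux = as<double>(par["k_influx"]);
  E.tauH = as<double>(par["tau_h"]);
  E.Nthres = as<int>(par["N_thres"]);
  E.Nmax = as<int>(par["N_NKG2D_max"]);
  E.clustering = as<int>(par["clustering"]);
  E.coclust = as<int>(par["coclustering"]);
  E.sConst1 = as<int>(par["s_const1"]);
  E.rimBindRate = as<double>(par["rim_bind_rate"]);
  E.rimKoff = as<double>(par["rim_koff"]);
  E.sVav1 = as<int>(par["vav1_index"]);
  E.sPVav1 = as<int>(par["pvav1_index"]);

  E.tree.init(E.NC + std::max(E.NR, 1));
  int nev = E.NCH + (int)E.diffSp.size() + 2 * (int)E.clustSp.size();
  E.scratch.assign(nev + 4, 0.0);
  E.rng.seed((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  E.t = 0.0;
  E.nReact = E.nDiff = E.nForm = E.nClustHop = E.nInflux = E.nReject =
      E.nRimReact = 0;
  E.rebuildAll();

  int nSnap = (int)snapTimes.size();
  List snaps(keepSnapshots ? nSnap : 0);
  NumericMatrix totals(nSnap, E.NS);
  NumericVector pvSeries(nSnap), centralSeries(nSnap), snapT(nSnap);
  // central 6x6-chamber block (3 um x 3 um for the default geometry)
  std::vector<int> centralCh;
  {
    int k = as<int>(par["central_chambers"]);
    int lo = nx / 2 - k / 2;
    for (int j = lo; j < lo + k && j < ny; ++j)
      for (int i = lo; i < lo + k && i < nx; ++i)
        if (i >= 0 && j >= 0) centralCh.push_back(i + nx * j);
  }

  double nextH = E.tauH;
  int snapIdx = 0;
  auto record = [&](double at_t) {
    snapT[snapIdx] = at_t;
    long long cc = 0;
    for (size_t q = 0; q < centralCh.size(); ++q)
      cc += E.nkTot[centralCh[q]];
    centralSeries[snapIdx] = (double)cc;
    pvSeries[snapIdx] = (double)E.PV;
    for (int s = 0; s < E.NS; ++s) {
      long long tt = 0;
      for (int c = 0; c < E.NC; ++c) tt += E.at(c, s);
      totals(snapIdx, s) = (double)tt;
    }
    if (keepSnapshots) {
      IntegerVector sc(E.cnt.begin(), E.cnt.end());
      snaps[snapIdx] = sc;
    }
    ++snapIdx;
  };

  while (true) {
    while (snapIdx < nSnap && snapTimes[snapIdx] <= E.t + 1e-12)
      record(snapTimes[snapIdx]);
    if (E.t >= tEnd) break;
    double nextDet = tEnd;
    if (snapIdx < nSnap && snapTimes[snapIdx] < nextDet)
      nextDet = snapTimes[snapIdx];
    bool doH = false;
    if (E.tauH > 0 && nextH <= nextDet) { nextDet = nextH; doH = true; }
    double A = E.tree.total();
    double dt = (A > 0) ? -std::log(1.0 - E.runif()) / A : R_PosInf;
    if (E.t + dt >= nextDet) {
      E.t = nextDet;
      if (doH && std::abs(nextDet - nextH) < 1e-12) {
        E.homogenize();
        nextH += E.tauH;
      }
      continue;
    }
    E.t += dt;
    double u = E.runif() * A;
    if (u >= A) u = std::nextafter(A, 0.0);
    int leaf = E.tree.sample(u);
    if (leaf < E.NC) E.executeChamberEvent(leaf);
    else if (leaf - E.NC < E.NR) E.executeRimEvent(leaf - E.NC);
  }
  while (snapIdx < nSnap) record(snapTimes[snapIdx]);

  // cache revalidation: recompute every propensity and compare totals
  double cached = E.tree.total();
  for (int c = 0; c < E.NC; ++c) E.refreshChamber(c);
  for (int r = 0; r < E.NR; ++r) E.refreshRim(r);
  double recomputed = E.tree.total();

  IntegerVector finalCnt(E.cnt.begin(), E.cnt.end());
  IntegerVector fRimN(E.rimN.begin(), E.rimN.end());
  IntegerVector fRimL(E.rimL.begin(), E.rimL.end());
  IntegerVector fRimC0(E.rimC0.begin(), E.rimC0.end());
  NumericVector events = NumericVector::create(
      Named("reaction") = (double)E.nReact,
      Named("diffusion") = (double)E.nDiff,
      Named("formation") = (double)E.nForm,
      Named("cluster_hop") = (double)E.nClustHop,
      Named("influx") = (double)E.nInflux,
      Named("rim_reaction") = (double)E.nRimReact,
      Named("rejected") = (double)E.nReject);
  return List::create(
      Named("times") = snapT, Named("snapshots") = snaps,
      Named("totals") = totals, Named("pvav1") = pvSeries,
      Named("central_nkg2d") = centralSeries,
      Named("final_counts") = finalCnt, Named("rim_N") = fRimN,
      Named("rim_L") = fRimL, Named("rim_C0") = fRimC0,
      Named("events") = events,
      Named("cached_total") = cached,
      Named("recomputed_total") = recomputed);
}
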