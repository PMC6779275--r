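// Direct-method SSA engine for DISC/RIPoptosome platform assembly, with
// three modes: assembly only, hybrid (SSA assembly + RK45 caspase cascade,
// fixed-step operator splitting) and full SSA (cascade reactions discrete).
//
// Counts are doubles (exact below 2^53). Propensities are organised by
// reaction family; per-platform weights live in Fenwick trees so one event
// costs O(log P). All randomness comes from a seeded mt19937_64 with
// explicit inverse-transform draws, so trajectories are bit-reproducible
// for a given seed across platforms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Fenwick {
  int n;
  std::vector<double> tree, val;
  void init(int n_) {
    n = n_;
    tree.assign(n + 1, 0.0);
    val.assign(std::max(n_, 1), 0.0);
  }
  void set(int i, double v) {
    double d = v - val[i];
    if (d == 0.0) return;
    val[i] = v;
    for (int k = i + 1; k <= n; k += k & (-k)) tree[k] += d;
  }
  double total() const {
    double s = 0.0;
    for (int k = n; k > 0; k -= k & (-k)) s += tree[k];
    return s;
  }
  // index i with prefix(i) < u <= prefix(i) + val[i]; robust to float drift
  int find(double u) const {
    int pos = 0;
    int logn = 0;
    while ((1 << (logn + 1)) <= n) ++logn;
    for (int pw = 1 << logn; pw > 0; pw >>= 1) {
      int nxt = pos + pw;
      if (nxt <= n && tree[nxt] < u) {
        u -= tree[nxt];
        pos = nxt;
      }
    }
    if (pos >= n) pos = n - 1;
    if (val[pos] <= 0.0) { // float-drift guard: nearest active entry
      for (int k = pos; k >= 0; --k) if (val[k] > 0.0) return k;
      for (int k = pos + 1; k < n; ++k) if (val[k] > 0.0) return k;
    }
    return pos;
  }
};

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double u01() { // 53-bit uniform in (0,1]
    return ((gen() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  double uexp(double rate) { return -std::log(u01()) / rate; }
};

// cascade state indices (order matches cascade_state_names in R)
enum { iC8D = 0, iC8M, iPC3, iC3, iPC6, iC6, iXF, iXC3, iC3DEG, iFI, iFC,
       iPC8, NY };

struct OdeParams {
  double kc8_3, kc3a, kc3_6, kc6_8, kdim8, koff8d, konx, koffx, kcatub, kdeg,
      kfret;
  bool regen;
};

inline void cascade_rhs_c(const double* y, double src, const OdeParams& p,
                          double* dy) {
  double c8d = y[iC8D] > 0 ? y[iC8D] : 0, c8m = y[iC8M] > 0 ? y[iC8M] : 0;
  double pc3 = y[iPC3] > 0 ? y[iPC3] : 0, c3 = y[iC3] > 0 ? y[iC3] : 0;
  double pc6 = y[iPC6] > 0 ? y[iPC6] : 0, c6 = y[iC6] > 0 ? y[iC6] : 0;
  double xf = y[iXF] > 0 ? y[iXF] : 0, xc3 = y[iXC3] > 0 ? y[iXC3] : 0;
  double fi = y[iFI] > 0 ? y[iFI] : 0, pc8 = y[iPC8] > 0 ? y[iPC8] : 0;
  double v_dim = p.kdim8 * c8m * c8m;
  double v_und = p.koff8d * c8d;
  double v_c3 = (p.kc8_3 * c8d + p.kc3a * c3) * pc3;
  double v_c6 = p.kc3_6 * c3 * pc6;
  double v_c8 = p.kc6_8 * c6 * pc8;
  double v_xon = p.konx * xf * c3;
  double v_xoff = p.koffx * xc3;
  double v_ub = p.kcatub * xc3;
  double v_fret = p.kfret * c8d * fi;
  double v_bas = p.kdeg * c3;
  dy[iC8D] = src + v_dim - v_und;
  dy[iC8M] = 2 * v_und - 2 * v_dim + v_c8;
  dy[iPC3] = -v_c3;
  dy[iC3] = v_c3 - v_xon + v_xoff - v_bas;
  dy[iPC6] = -v_c6;
  dy[iC6] = v_c6;
  dy[iXF] = -v_xon + v_xoff + (p.regen ? v_ub : 0.0);
  dy[iXC3] = v_xon - v_xoff - v_ub;
  dy[iC3DEG] = v_ub + v_bas;
  dy[iFI] = -v_fret;
  dy[iFC] = v_fret;
  dy[iPC8] = -v_c8;
}

// Cash-Karp embedded RK45 with adaptive step over [0, h_total]
void rk45_advance(double* y, double h_total, double src, const OdeParams& p) {
  static const double b21 = 1.0 / 5;
  static const double b31 = 3.0 / 40, b32 = 9.0 / 40;
  static const double b41 = 3.0 / 10, b42 = -9.0 / 10, b43 = 6.0 / 5;
  static const double b51 = -11.0 / 54, b52 = 5.0 / 2, b53 = -70.0 / 27,
                      b54 = 35.0 / 27;
  static const double b61 = 1631.0 / 55296, b62 = 175.0 / 512,
                      b63 = 575.0 / 13824, b64 = 44275.0 / 110592,
                      b65 = 253.0 / 4096;
  static const double c1 = 37.0 / 378, c3 = 250.0 / 621, c4 = 125.0 / 594,
                      c6 = 512.0 / 1771;
  static const double d1 = c1 - 2825.0 / 27648, d3 = c3 - 18575.0 / 48384,
                      d4 = c4 - 13525.0 / 55296, d5 = -277.0 / 14336,
                      d6 = c6 - 1.0 / 4;
  const double rtol = 1e-6, atol = 1e-10;
  double t = 0.0, h = h_total;
  double k1[NY], k2[NY], k3[NY], k4[NY], k5[NY], k6[NY], yt[NY], ynew[NY];
  int guard = 0;
  while (t < h_total && ++guard < 200000) {
    if (t + h > h_total) h = h_total - t;
    cascade_rhs_c(y, src, p, k1);
    for (int i = 0; i < NY; ++i) yt[i] = y[i] + h * b21 * k1[i];
    cascade_rhs_c(yt, src, p, k2);
    for (int i = 0; i < NY; ++i)
      yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    cascade_rhs_c(yt, src, p, k3);
    for (int i = 0; i < NY; ++i)
      yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    cascade_rhs_c(yt, src, p, k4);
    for (int i = 0; i < NY; ++i)
      yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                          b54 * k4[i]);
    cascade_rhs_c(yt, src, p, k5);
    for (int i = 0; i < NY; ++i)
      yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                          b64 * k4[i] + b65 * k5[i]);
    cascade_rhs_c(yt, src, p, k6);
    double errmax = 0.0;
    for (int i = 0; i < NY; ++i) {
      ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      double err = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                        d6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      errmax = std::max(errmax, std::fabs(err) / sc);
    }
    if (errmax <= 1.0 || h <= 1e-8) {
      t += h;
      for (int i = 0; i < NY; ++i) y[i] = ynew[i] > 0 ? ynew[i] : 0.0;
      double fac = errmax > 0 ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(errmax, -0.25));
    }
  }
}

// reaction family ids
enum Fam {
  F_ELONG = 0, F_R1OFF, F_R3ON, F_R3OFF, F_FON, F_FOFF, F_C8ON, F_C8OFF,
  F_FLLON, F_FLLOFF, F_FLSON, F_FLSOFF, F_DEDON, F_DEDOFF, F_CAPC8,
  F_CAPDED, F_CAPOFF, F_CIS, F_HET, F_TRANS, F_ACT, F_DIMOFF, F_HETACT,
  NFAM_ASSEMBLY,
  // full-SSA cascade families (global, scalar)
  C_UND = NFAM_ASSEMBLY, C_DIM, C_C8C3, C_AUTO, C_C3C6, C_C6C8, C_XON,
  C_XOFF, C_UB, C_BAS, C_FRET, NFAM
};

struct Engine {
  // assembly rates (molecule units)
  double c_el, k_r1off, c_r3, k_r3off, c_f, k_foff, c_c8, k_c8off, c_fll,
      k_flloff, c_fls, k_flsoff, c_ded, k_dedoff, c_cap, k_capoff, k_cis,
      k_trans, k_het, k_act, k_dimoff;
  bool het_active;
  double conv;
  OdeParams ode;

  int P;
  std::vector<int> nR1, nR3, nF, nC8, nFLl, nFLs, nDED, capv, clu;
  std::vector<std::vector<int> > members;
  std::vector<double> Scl, Qcl;
  double RIP1f, RIP3f, FADDf, PC8f, FLlf, FLsf, DEDf;
  double nDimPend, nHetL, nHetS, nHetD;
  double cumC8, cumDED, cumHet, cumDebit;
  Fenwick fOpen, fR1off, fR3on, fR3off, fFon, fFree, fC8, fFLl, fFLs, fDED,
      fCapped, fCis, fHet, fClu;
  double yc[NY]; // cascade state: nM (modes 0/1) or counts (mode 2)
  int clamp_events = 0;

  int occ(int i) const { return nC8[i] + nFLl[i] + nFLs[i] + nDED[i]; }

  void cluster_refresh(int c) {
    double S = 0, Q = 0;
    for (size_t k = 0; k < members[c].size(); ++k) {
      double v = nC8[members[c][k]];
      S += v;
      Q += v * v;
    }
    Scl[c] = S;
    Qcl[c] = Q;
    double w = (S * S - Q) / 2.0;
    fClu.set(c, w > 0 ? w : 0.0);
  }

  void refresh(int i) {
    bool open = capv[i] == 0;
    int fr = nF[i] - occ(i);
    if (fr < 0) fr = 0;
    fOpen.set(i, open ? 1.0 : 0.0);
    fR1off.set(i, (open && nR1[i] > 1) ? 1.0 : 0.0);
    fR3on.set(i, std::max(nR1[i] - nR3[i], 0));
    fR3off.set(i, nR3[i]);
    fFon.set(i, std::max(nR1[i] - nF[i], 0));
    fFree.set(i, fr);
    fC8.set(i, nC8[i]);
    fFLl.set(i, nFLl[i]);
    fFLs.set(i, nFLs[i]);
    fDED.set(i, nDED[i]);
    fCapped.set(i, capv[i] > 0 ? 1.0 : 0.0);
    fCis.set(i, nC8[i] * (nC8[i] - 1) / 2.0);
    fHet.set(i, (double)nC8[i] * (nFLl[i] + nFLs[i] + nDED[i]));
    if (k_trans > 0 && members[clu[i]].size() > 1) cluster_refresh(clu[i]);
  }

  void family_propensities(double* a, bool full_ssa) {
    double openTot = fOpen.total();
    double freeTot = fFree.total();
    a[F_ELONG] = c_el * RIP1f * openTot;
    a[F_R1OFF] = k_r1off * fR1off.total();
    a[F_R3ON] = c_r3 * RIP3f * fR3on.total();
    a[F_R3OFF] = k_r3off * fR3off.total();
    a[F_FON] = c_f * FADDf * fFon.total();
    a[F_FOFF] = k_foff * freeTot;
    a[F_C8ON] = c_c8 * PC8f * freeTot;
    a[F_C8OFF] = k_c8off * fC8.total();
    a[F_FLLON] = c_fll * FLlf * freeTot;
    a[F_FLLOFF] = k_flloff * fFLl.total();
    a[F_FLSON] = c_fls * FLsf * freeTot;
    a[F_FLSOFF] = k_flsoff * fFLs.total();
    a[F_DEDON] = c_ded * DEDf * freeTot;
    a[F_DEDOFF] = k_dedoff * fDED.total();
    a[F_CAPC8] = c_cap * PC8f * openTot;
    a[F_CAPDED] = c_cap * DEDf * openTot;
    a[F_CAPOFF] = k_capoff * fCapped.total();
    a[F_CIS] = k_cis * fCis.total();
    a[F_HET] = k_het * fHet.total();
    a[F_TRANS] = k_trans > 0 ? k_trans * fClu.total() : 0.0;
    a[F_ACT] = k_act * nDimPend;
    a[F_DIMOFF] = k_dimoff * nDimPend;
    a[F_HETACT] = het_active ? k_act * nHetL : 0.0;
    if (full_ssa) {
      const OdeParams& p = ode;
      double cv = conv;
      a[C_UND] = p.koff8d * yc[iC8D];
      a[C_DIM] = p.kdim8 / cv * yc[iC8M] * std::max(yc[iC8M] - 1.0, 0.0);
      a[C_C8C3] = p.kc8_3 / cv * yc[iC8D] * yc[iPC3];
      a[C_AUTO] = p.kc3a / cv * yc[iC3] * yc[iPC3];
      a[C_C3C6] = p.kc3_6 / cv * yc[iC3] * yc[iPC6];
      a[C_C6C8] = p.kc6_8 / cv * yc[iC6] * PC8f;
      a[C_XON] = p.konx / cv * yc[iXF] * yc[iC3];
      a[C_XOFF] = p.koffx * yc[iXC3];
      a[C_UB] = p.kcatub * yc[iXC3];
      a[C_BAS] = p.kdeg * yc[iC3];
      a[C_FRET] = p.kfret / cv * yc[iC8D] * yc[iFI];
    } else {
      for (int f = NFAM_ASSEMBLY; f < NFAM; ++f) a[f] = 0.0;
    }
  }

  // returns 1 when the event releases an active Casp8 dimer
  int apply(int fam, double u_resid, Rng& rng, bool full_ssa) {
    int released = 0;
    switch (fam) {
      case F_ELONG: {
        int i = fOpen.find(u_resid / (c_el * RIP1f));
        RIP1f -= 1; nR1[i] += 1; refresh(i); break;
      }
      case F_R1OFF: {
        int i = fR1off.find(u_resid / k_r1off);
        RIP1f += 1; nR1[i] -= 1; refresh(i); break;
      }
      case F_R3ON: {
        int i = fR3on.find(u_resid / (c_r3 * RIP3f));
        RIP3f -= 1; nR3[i] += 1; cumHet += 1; refresh(i); break;
      }
      case F_R3OFF: {
        int i = fR3off.find(u_resid / k_r3off);
        RIP3f += 1; nR3[i] -= 1; refresh(i); break;
      }
      case F_FON: {
        int i = fFon.find(u_resid / (c_f * FADDf));
        FADDf -= 1; nF[i] += 1; refresh(i); break;
      }
      case F_FOFF: {
        int i = fFree.find(u_resid / k_foff);
        FADDf += 1; nF[i] -= 1; refresh(i); break;
      }
      case F_C8ON: {
        int i = fFree.find(u_resid / (c_c8 * PC8f));
        PC8f -= 1; nC8[i] += 1; refresh(i); break;
      }
      case F_C8OFF: {
        int i = fC8.find(u_resid / k_c8off);
        PC8f += 1; nC8[i] -= 1; refresh(i); break;
      }
      case F_FLLON: {
        int i = fFree.find(u_resid / (c_fll * FLlf));
        FLlf -= 1; nFLl[i] += 1; refresh(i); break;
      }
      case F_FLLOFF: {
        int i = fFLl.find(u_resid / k_flloff);
        FLlf += 1; nFLl[i] -= 1; refresh(i); break;
      }
      case F_FLSON: {
        int i = fFree.find(u_resid / (c_fls * FLsf));
        FLsf -= 1; nFLs[i] += 1; refresh(i); break;
      }
      case F_FLSOFF: {
        int i = fFLs.find(u_resid / k_flsoff);
        FLsf += 1; nFLs[i] -= 1; refresh(i); break;
      }
      case F_DEDON: {
        int i = fFree.find(u_resid / (c_ded * DEDf));
        DEDf -= 1; nDED[i] += 1; refresh(i); break;
      }
      case F_DEDOFF: {
        int i = fDED.find(u_resid / k_dedoff);
        DEDf += 1; nDED[i] -= 1; refresh(i); break;
      }
      case F_CAPC8: {
        int i = fOpen.find(u_resid / (c_cap * PC8f));
        PC8f -= 1; capv[i] = 1; refresh(i); break;
      }
      case F_CAPDED: {
        int i = fOpen.find(u_resid / (c_cap * DEDf));
        DEDf -= 1; capv[i] = 2; refresh(i); break;
      }
      case F_CAPOFF: {
        int i = fCapped.find(u_resid / k_capoff);
        if (capv[i] == 1) PC8f += 1; else DEDf += 1;
        capv[i] = 0; refresh(i); break;
      }
      case F_CIS: {
        int i = fCis.find(u_resid / k_cis);
        nC8[i] -= 2; nDimPend += 1; refresh(i); break;
      }
      case F_HET: {
        int i = fHet.find(u_resid / k_het);
        nC8[i] -= 1;
        // partner drawn proportional to bound dead-DED competitors
        double pl = nFLl[i], ps = nFLs[i], pd = nDED[i];
        double u2 = rng.u01() * (pl + ps + pd);
        if (u2 < pl) { nFLl[i] -= 1; nHetL += 1; }
        else if (u2 < pl + ps) { nFLs[i] -= 1; nHetS += 1; }
        else { nDED[i] -= 1; nHetD += 1; }
        refresh(i); break;
      }
      case F_TRANS: {
        int c = fClu.find(u_resid / k_trans);
        const std::vector<int>& mem = members[c];
        double uS = rng.u01() * Scl[c];
        int i = mem[0];
        for (size_t k = 0; k < mem.size(); ++k) {
          uS -= nC8[mem[k]];
          if (uS <= 0) { i = mem[k]; break; }
        }
        double S2 = Scl[c] - nC8[i];
        double uJ = rng.u01() * S2;
        int j = -1;
        for (size_t k = 0; k < mem.size(); ++k) {
          if (mem[k] == i) continue;
          uJ -= nC8[mem[k]];
          if (uJ <= 0) { j = mem[k]; break; }
        }
        if (j < 0) {
          for (size_t k = 0; k < mem.size(); ++k)
            if (mem[k] != i && nC8[mem[k]] > 0) { j = mem[k]; break; }
        }
        if (j < 0) break;
        nC8[i] -= 1; nC8[j] -= 1; nDimPend += 1;
        refresh(i); refresh(j);
        break;
      }
      case F_ACT: {
        nDimPend -= 1; cumC8 += 1; DEDf += 1; cumDED += 1;
        released = 1;
        if (full_ssa) yc[iC8D] += 1;
        break;
      }
      case F_DIMOFF: {
        nDimPend -= 1; PC8f += 2; break;
      }
      case F_HETACT: {
        nHetL -= 1; cumC8 += 1; DEDf += 1; cumDED += 1;
        released = 1;
        if (full_ssa) yc[iC8D] += 1;
        break;
      }
      // --- full-SSA cascade reactions (counts) ---
      case C_UND: yc[iC8D] -= 1; yc[iC8M] += 2; break;
      case C_DIM: yc[iC8M] -= 2; yc[iC8D] += 1; break;
      case C_C8C3: yc[iPC3] -= 1; yc[iC3] += 1; break;
      case C_AUTO: yc[iPC3] -= 1; yc[iC3] += 1; break;
      case C_C3C6: yc[iPC6] -= 1; yc[iC6] += 1; break;
      case C_C6C8: PC8f -= 1; yc[iC8M] += 1; break;
      case C_XON: yc[iXF] -= 1; yc[iC3] -= 1; yc[iXC3] += 1; break;
      case C_XOFF: yc[iXF] += 1; yc[iC3] += 1; yc[iXC3] -= 1; break;
      case C_UB:
        yc[iXC3] -= 1; yc[iC3DEG] += 1;
        if (ode.regen) yc[iXF] += 1;
        break;
      case C_BAS: yc[iC3] -= 1; yc[iC3DEG] += 1; break;
      case C_FRET: yc[iFI] -= 1; yc[iFC] += 1; break;
    }
    return released;
  }

  double mass_of(int i, const std::vector<double>& m) const {
    double cm = capv[i] == 1 ? m[3] : (capv[i] == 2 ? m[6] : 0.0);
    return nR1[i] * m[0] + nR3[i] * m[1] + nF[i] * m[2] + nC8[i] * m[3] +
           nFLl[i] * m[4] + nFLs[i] * m[5] + nDED[i] * m[6] + cm;
  }

  // mode-aware species-conservation ledgers
  void check_ledgers(const std::vector<double>& tot, int mode) const {
    double sR1 = RIP1f, sR3 = RIP3f, sF = FADDf, sC8 = PC8f, sL = FLlf,
           sS = FLsf, sD = DEDf;
    int nCapC8 = 0, nCapD = 0;
    for (int i = 0; i < P; ++i) {
      sR1 += nR1[i]; sR3 += nR3[i]; sF += nF[i]; sC8 += nC8[i];
      sL += nFLl[i]; sS += nFLs[i]; sD += nDED[i];
      if (capv[i] == 1) ++nCapC8;
      if (capv[i] == 2) ++nCapD;
      if (nR1[i] < 1 || nR3[i] < 0 || nF[i] < 0 || nC8[i] < 0 ||
          nFLl[i] < 0 || nFLs[i] < 0 || nDED[i] < 0)
        stop("negative platform count");
      if (nF[i] - occ(i) < 0) stop("DED-site occupancy exceeds FADD count");
    }
    if (RIP1f < 0 || RIP3f < 0 || FADDf < 0 || PC8f < 0 || FLlf < 0 ||
        FLsf < 0 || DEDf < 0 || nDimPend < 0 || nHetL < 0 || nHetS < 0 ||
        nHetD < 0)
      stop("negative free pool");
    sC8 += nCapC8 + 2 * nDimPend + nHetL + nHetS + nHetD;
    if (mode == 2) sC8 += 2 * yc[iC8D] + yc[iC8M];
    else sC8 += 2 * cumC8 + cumDebit;
    bool skip_c8 = het_active && cumC8 > 0; // het activation mixes ledgers
    if (std::fabs(sR1 - tot[0]) > 1e-6) stop("RIP1 conservation violated");
    if (std::fabs(sR3 - tot[1]) > 1e-6) stop("RIP3 conservation violated");
    if (std::fabs(sF - tot[2]) > 1e-6) stop("FADD conservation violated");
    if (!skip_c8 && std::fabs(sC8 - tot[3]) > 1e-6)
      stop("ProCasp8 conservation violated");
    if (std::fabs(sL + nHetL - tot[4]) > 1e-6)
      stop("cFLIPl conservation violated");
    if (std::fabs(sS + nHetS - tot[5]) > 1e-6)
      stop("cFLIPs conservation violated");
    if (!skip_c8 && std::fabs((sD + nCapD + nHetD - cumDED) - tot[6]) > 1e-6)
      stop("DED1-DED2 conservation violated");
  }
};

} // namespace

// [[Rcpp::export(name = ".engine_simulate_cell")]]
List engine_simulate_cell(List spec) {
  Engine E;
  List rates = spec["rates"];
  E.c_el = as<double>(rates["c_el"]);
  E.k_r1off = as<double>(rates["k_r1off"]);
  E.c_r3 = as<double>(rates["c_r3"]);
  E.k_r3off = as<double>(rates["k_r3off"]);
  E.c_f = as<double>(rates["c_f"]);
  E.k_foff = as<double>(rates["k_foff"]);
  E.c_c8 = as<double>(rates["c_c8"]);
  E.k_c8off = as<double>(rates["k_c8off"]);
  E.c_fll = as<double>(rates["c_fll"]);
  E.k_flloff = as<double>(rates["k_flloff"]);
  E.c_fls = as<double>(rates["c_fls"]);
  E.k_flsoff = as<double>(rates["k_flsoff"]);
  E.c_ded = as<double>(rates["c_ded"]);
  E.k_dedoff = as<double>(rates["k_dedoff"]);
  E.c_cap = as<double>(rates["c_cap"]);
  E.k_capoff = as<double>(rates["k_capoff"]);
  E.k_cis = as<double>(rates["k_cis"]);
  E.k_trans = as<double>(rates["k_trans"]);
  E.k_het = as<double>(rates["k_het"]);
  E.k_act = as<double>(rates["k_act"]);
  E.k_dimoff = as<double>(rates["k_dimoff"]);
  E.het_active = as<bool>(rates["het_active"]);
  E.conv = as<double>(rates["conv"]);

  List op = spec["ode_params"];
  E.ode.kc8_3 = as<double>(op["k_casp8_casp3_nm_min"]);
  E.ode.kc3a = as<double>(op["k_casp3_auto_nm_min"]);
  E.ode.kc3_6 = as<double>(op["k_casp3_casp6_nm_min"]);
  E.ode.kc6_8 = as<double>(op["k_casp6_casp8_nm_min"]);
  E.ode.kdim8 = as<double>(op["k_casp8_mono_dimer_nm_min"]);
  E.ode.koff8d = as<double>(op["koff_casp8_dimer_min"]);
  E.ode.konx = as<double>(op["kon_xiap_casp3_nm_min"]);
  E.ode.koffx = as<double>(op["koff_xiap_casp3_min"]);
  E.ode.kcatub = as<double>(op["kcat_ub_min"]);
  E.ode.kdeg = as<double>(op["k_basal_deg_min"]);
  E.ode.kfret = as<double>(op["k_fret_cleave_nm_min"]);
  E.ode.regen = as<bool>(spec["xiap_regenerated"]);

  NumericVector pools = spec["pools"];
  E.RIP1f = pools["rip1"];
  E.RIP3f = pools["rip3"];
  E.FADDf = pools["fadd"];
  E.PC8f = pools["procasp8"];
  E.FLlf = pools["cflip_l"];
  E.FLsf = pools["cflip_s"];
  E.DEDf = pools["ded12"];
  E.nDimPend = E.nHetL = E.nHetS = E.nHetD = 0;
  E.cumC8 = E.cumDED = E.cumHet = E.cumDebit = 0;

  IntegerVector cluster_id = spec["cluster_id"]; // 1-based
  int P = cluster_id.size();
  E.P = P;
  E.nR1.assign(P, 1); E.nR3.assign(P, 0); E.nF.assign(P, 0);
  E.nC8.assign(P, 0); E.nFLl.assign(P, 0); E.nFLs.assign(P, 0);
  E.nDED.assign(P, 0); E.capv.assign(P, 0); E.clu.assign(P, 0);
  int K = 0;
  for (int i = 0; i < P; ++i) K = std::max(K, cluster_id[i]);
  E.members.assign(std::max(K, 1), std::vector<int>());
  for (int i = 0; i < P; ++i) {
    E.clu[i] = cluster_id[i] - 1;
    E.members[E.clu[i]].push_back(i);
  }
  E.Scl.assign(std::max(K, 1), 0.0);
  E.Qcl.assign(std::max(K, 1), 0.0);
  E.fOpen.init(P); E.fR1off.init(P); E.fR3on.init(P); E.fR3off.init(P);
  E.fFon.init(P); E.fFree.init(P); E.fC8.init(P); E.fFLl.init(P);
  E.fFLs.init(P); E.fDED.init(P); E.fCapped.init(P); E.fCis.init(P);
  E.fHet.init(P); E.fClu.init(std::max(K, 1));
  for (int i = 0; i < P; ++i) E.refresh(i);

  std::vector<double> masses = as<std::vector<double> >(spec["masses"]);
  bool validate = as<bool>(spec["validate"]);
  std::vector<double> totals(7);
  totals[0] = E.RIP1f + P; totals[1] = E.RIP3f; totals[2] = E.FADDf;
  totals[3] = E.PC8f; totals[4] = E.FLlf; totals[5] = E.FLsf;
  totals[6] = E.DEDf;

  int mode = as<int>(spec["mode"]); // 0 assembly, 1 hybrid, 2 full SSA
  double t_max = as<double>(spec["t_max"]);
  double dt_sync = as<double>(spec["dt_sync"]);
  double record_dt = as<double>(spec["record_dt"]);
  double thr = as<double>(spec["threshold"]); // nM/min; <= 0 disables
  bool record_origins = as<bool>(spec["record_origins"]);
  uint64_t seed = (uint64_t)as<double>(spec["seed"]);
  Rng rng(seed ^ 0x9e3779b97f4a7c15ULL);

  NumericVector y0 = spec["y0"];
  for (int i = 0; i < NY; ++i) E.yc[i] = y0[i];
  if (mode == 2) { // cascade in counts; ProCasp8 shared with assembly pool
    for (int i = 0; i < NY; ++i) E.yc[i] = std::floor(E.yc[i] * E.conv + 0.5);
    E.yc[iPC8] = 0;
  } else {
    E.yc[iPC8] = E.PC8f / E.conv;
  }

  int n_rec = (int)std::floor(t_max / record_dt + 1e-9) + 1;
  const int NCOL = 35;
  NumericMatrix series(n_rec, NCOL);
  NumericVector rec_time(n_rec);
  std::vector<IntegerMatrix> orig;
  if (record_origins) {
    for (int f = 0; f < 8; ++f) orig.push_back(IntegerMatrix(n_rec, P));
  }

  double a[NFAM];
  double t = 0.0;
  int rec_i = 0;
  bool died = false;
  double death_time = NA_REAL;
  double prev_rate = 0.0, prev_rate_t = 0.0;
  double pc8_debt = 0.0;
  double released_in_window = 0;
  long long n_events = 0;
  // window cadence: cascade sync for hybrid/full-SSA, record grid otherwise
  double window = (mode == 0) ? record_dt : dt_sync;

  auto do_record = [&](double tt) {
    if (rec_i >= n_rec) return;
    rec_time[rec_i] = tt;
    double bF = 0, bC8 = 0, bR1 = 0, bR3 = 0, bFLl = 0, bFLs = 0, bD = 0;
    double mx = 0; int n2m = 0;
    for (int i = 0; i < P; ++i) {
      bF += E.nF[i]; bC8 += E.nC8[i]; bR1 += E.nR1[i]; bR3 += E.nR3[i];
      bFLl += E.nFLl[i]; bFLs += E.nFLs[i]; bD += E.nDED[i];
      double m = E.mass_of(i, masses);
      if (m > mx) mx = m;
      if (m >= 2000.0) ++n2m;
    }
    series(rec_i, 0) = E.cumC8; series(rec_i, 1) = E.cumDED;
    series(rec_i, 2) = E.cumHet; series(rec_i, 3) = E.nDimPend;
    series(rec_i, 4) = E.RIP1f; series(rec_i, 5) = E.RIP3f;
    series(rec_i, 6) = E.FADDf; series(rec_i, 7) = E.PC8f;
    series(rec_i, 8) = E.FLlf; series(rec_i, 9) = E.FLsf;
    series(rec_i, 10) = E.DEDf;
    series(rec_i, 11) = bF; series(rec_i, 12) = bC8;
    series(rec_i, 13) = P ? bF / P : 0; series(rec_i, 14) = P ? bC8 / P : 0;
    series(rec_i, 15) = mx; series(rec_i, 16) = n2m;
    series(rec_i, 17) = P ? bR1 / P : 0; series(rec_i, 18) = P ? bR3 / P : 0;
    series(rec_i, 19) = P ? bFLl / P : 0;
    series(rec_i, 20) = P ? bFLs / P : 0; series(rec_i, 21) = P ? bD / P : 0;
    double cv2 = (mode == 2) ? E.conv : 1.0;
    for (int k = 0; k < NY; ++k) {
      double v = (k == iPC8 && mode == 2) ? E.PC8f / E.conv : E.yc[k] / cv2;
      series(rec_i, 22 + k) = v;
    }
    series(rec_i, 34) =
        (mode == 0) ? 0.0
                    : E.ode.kfret * series(rec_i, 22 + iC8D) *
                          series(rec_i, 22 + iFI);
    if (record_origins) {
      for (int i = 0; i < P; ++i) {
        orig[0](rec_i, i) = E.nR1[i]; orig[1](rec_i, i) = E.nR3[i];
        orig[2](rec_i, i) = E.nF[i]; orig[3](rec_i, i) = E.nC8[i];
        orig[4](rec_i, i) = E.nFLl[i]; orig[5](rec_i, i) = E.nFLs[i];
        orig[6](rec_i, i) = E.nDED[i]; orig[7](rec_i, i) = E.capv[i];
      }
    }
    ++rec_i;
  };

  do_record(0.0);
  long long win = 0;
  long long n_windows = (long long)std::floor(t_max / window + 1e-9);
  while (win < n_windows && !died) {
    double window_end = (double)(win + 1) * window;
    // --- SSA phase over [t, window_end] ---
    while (true) {
      E.family_propensities(a, mode == 2);
      double a0 = 0.0;
      for (int f = 0; f < NFAM; ++f) a0 += a[f];
      if (a0 <= 0.0) { t = window_end; break; }
      double dt = rng.uexp(a0);
      if (t + dt > window_end) { t = window_end; break; }
      t += dt;
      double u = rng.u01() * a0;
      int fam = 0;
      while (fam < NFAM - 1 && u > a[fam]) { u -= a[fam]; ++fam; }
      released_in_window += E.apply(fam, u, rng, mode == 2);
      ++n_events;
      if (validate && n_events % 1024 == 0) E.check_ledgers(totals, mode);
    }
    // --- ODE phase (hybrid only) ---
    if (mode == 1) {
      double src = released_in_window / E.conv / window;
      released_in_window = 0;
      double pc8_before = E.PC8f / E.conv;
      E.yc[iPC8] = pc8_before;
      rk45_advance(E.yc, window, src, E.ode);
      double cleaved = pc8_before - E.yc[iPC8];
      if (cleaved > 0) {
        pc8_debt += cleaved * E.conv;
        double whole = std::floor(pc8_debt);
        if (whole > 0) {
          pc8_debt -= whole;
          E.cumDebit += whole;
          E.PC8f -= whole;
          if (E.PC8f < 0) {
            E.cumDebit += E.PC8f;
            E.PC8f = 0;
            ++E.clamp_events;
          }
        }
      }
    }
    // --- record on the output grid ---
    while (rec_i < n_rec && rec_i * record_dt <= window_end + 1e-9) {
      do_record(rec_i * record_dt);
    }
    // --- death check at the window boundary ---
    if (mode != 0 && thr > 0) {
      double c8d_nm = (mode == 2) ? E.yc[iC8D] / E.conv : E.yc[iC8D];
      double fi_nm = (mode == 2) ? E.yc[iFI] / E.conv : E.yc[iFI];
      double rate = E.ode.kfret * c8d_nm * fi_nm;
      if (rate >= thr) {
        died = true;
        if (rate > prev_rate && prev_rate < thr) {
          double frac = (thr - prev_rate) / (rate - prev_rate);
          death_time = prev_rate_t + frac * (window_end - prev_rate_t);
        } else {
          death_time = window_end;
        }
      }
      prev_rate = rate;
      prev_rate_t = window_end;
    }
    ++win;
  }
  if (validate) E.check_ledgers(totals, mode);

  int keep = std::max(rec_i, 1);
  NumericMatrix series_out(keep, NCOL);
  NumericVector time_out(keep);
  for (int r = 0; r < keep; ++r) {
    time_out[r] = rec_time[r];
    for (int c = 0; c < NCOL; ++c) series_out(r, c) = series(r, c);
  }

  IntegerMatrix plat(P, 9);
  for (int i = 0; i < P; ++i) {
    plat(i, 0) = E.nR1[i]; plat(i, 1) = E.nR3[i]; plat(i, 2) = E.nF[i];
    plat(i, 3) = E.nC8[i]; plat(i, 4) = E.nFLl[i]; plat(i, 5) = E.nFLs[i];
    plat(i, 6) = E.nDED[i]; plat(i, 7) = E.capv[i]; plat(i, 8) = E.clu[i] + 1;
  }

  List out = List::create(
      _["time"] = time_out, _["series"] = series_out, _["platforms"] = plat,
      _["died"] = died, _["death_time"] = death_time,
      _["n_events"] = (double)n_events, _["clamp_events"] = E.clamp_events);
  if (record_origins) {
    std::vector<IntegerMatrix> otr;
    for (int f = 0; f < 8; ++f) {
      IntegerMatrix m(keep, P);
      for (int r = 0; r < keep; ++r)
        for (int i = 0; i < P; ++i) m(r, i) = orig[f](r, i);
      otr.push_back(m);
    }
    out["origins"] = List::create(
        _["n_rip1"] = otr[0], _["n_rip3"] = otr[1], _["n_fadd"] = otr[2],
        _["n_procasp8"] = otr[3], _["n_cflip_l"] = otr[4],
        _["n_cflip_s"] = otr[5], _["n_ded12"] = otr[6], _["cap"] = otr[7]);
  }
  return out;
}
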