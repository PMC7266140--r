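// Time-stepped simulation engine for stochastic point-neuron networks with
// delayed delta-synapse delivery, pair-based STDP (exponential windows with a
// constant negative offset), disinhibition-gated plasticity, short-term
// depressing synapses and deterministic leaky integrate-and-fire readouts.
//
// The engine advances a list of populations through a sequence of "phases";
// within one phase the inhibition state of every space, the Poisson input
// rates and the recording flag are constant.  All state that must survive a
// phase boundary (membrane potentials, excitability biases, refractory
// clocks, in-flight spikes, pairing histories) lives inside one engine call,
// so a protocol is executed as a single call with many phases.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ with splitmix64 stream derivation.  One independent
// stream per population so that adding a population never perturbs the
// realizations of the others.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  void seed(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// ---------------------------------------------------------------------------
// Populations
// ---------------------------------------------------------------------------

enum PopKind { POP_HAZARD = 0, POP_POISSON = 1, POP_LIF = 2 };

struct Pop {
  int kind, n, space; // space: 0-based index or -1
  // hazard params
  double c1, c2, c3, tau_m, R_m, I_e, q_sfa, tau_sfa_ms, b_max;
  // lif params
  double v_rest, v_thresh, refr_ms;
  // state
  std::vector<double> V, bsfa, refr_rem, refr_dur;
  // derived
  double decay, bdecay, drive_coef; // drive_coef = (1 - decay) * R_m
  double drive_const;               // per phase: drive_coef * (I_e + I_inh)
  // delayed jump ring (L slots x n)
  std::vector<double> J;
  // spike history per neuron (circular, step times)
  std::vector<int32_t> hist;
  std::vector<int32_t> hpos, hcnt;
  // spike list ring for constant-delay pre-arrival pairing
  std::vector<std::vector<int> > spike_ring;
  std::vector<int> cur;
  // per-phase poisson spike prob
  std::vector<double> pois_p;
  Rng rng;
};

static const int HIST_CAP = 256;

// ---------------------------------------------------------------------------
// Synapse groups
// ---------------------------------------------------------------------------

enum GrpKind { GRP_STATIC = 0, GRP_STDP = 1, GRP_TM = 2 };

struct Group {
  int kind, pre_pop, post_pop;
  double w_unit; // mV of membrane-potential jump per tabulated weight unit
  std::vector<int> pre, post, dstep;
  std::vector<double> w;
  bool plastic, frozen;
  bool active; // per phase (gate)
  double eta, alpha, A_minus, w_min, w_max;
  int Wsteps, const_delay; // const_delay in steps, -1 if per-edge
  std::vector<double> expP, expM;
  // CSR by pre neuron and by post neuron (indices into edge arrays)
  std::vector<int> preOff, preIdx, postOff, postIdx;
  // short-term depression state
  double U, tau_rec, tau_fac;
  std::vector<double> tmx, tmu;
  std::vector<int64_t> tm_last;
  std::vector<std::vector<int> > tm_ring;
};

static void build_csr(const std::vector<int> &key, int nkey,
                      std::vector<int> &off, std::vector<int> &idx) {
  int ne = (int)key.size();
  off.assign(nkey + 1, 0);
  for (int e = 0; e < ne; ++e) off[key[e] + 1]++;
  for (int k = 0; k < nkey; ++k) off[k + 1] += off[k];
  idx.resize(ne);
  std::vector<int> cur(off.begin(), off.end() - 1);
  for (int e = 0; e < ne; ++e) idx[cur[key[e]]++] = e;
}

static double num_or(const List &l, const char *name, double dflt) {
  if (!l.containsElementNamed(name)) return dflt;
  RObject o = l[name];
  if (o.isNULL()) return dflt;
  double v = as<double>(o);
  if (!R_finite(v)) return dflt;
  return v;
}

// [[Rcpp::export]]
List cpp_simulate(List pops_in, List groups_in, List spaces_in, List phases_in,
                  double dt, double w_unit, double seed) {
  const int npop = pops_in.size();
  const int ngrp = groups_in.size();
  const int nspace = spaces_in.size();
  const int nphase = phases_in.size();
  const double dt_s = dt * 1e-3;

  std::vector<Pop> pops(npop);
  std::vector<Group> grps(ngrp);

  // --- parse groups first to learn the maximum delay -----------------------
  int max_d = 1;
  for (int g = 0; g < ngrp; ++g) {
    List gl = groups_in[g];
    Group &G = grps[g];
    G.kind = as<int>(gl["kind"]);
    G.pre_pop = as<int>(gl["pre_pop"]) - 1;
    G.post_pop = as<int>(gl["post_pop"]) - 1;
    IntegerVector pre = gl["pre"], post = gl["post"];
    NumericVector w = gl["w"], del = gl["delay_ms"];
    int ne = pre.size();
    G.pre.resize(ne); G.post.resize(ne); G.w.resize(ne); G.dstep.resize(ne);
    for (int e = 0; e < ne; ++e) {
      G.pre[e] = pre[e] - 1;
      G.post[e] = post[e] - 1;
      G.w[e] = w[e];
      int d = (int)std::lround(del[e] / dt);
      if (d < 1) d = 1;
      G.dstep[e] = d;
      if (d > max_d) max_d = d;
    }
    G.w_unit = num_or(gl, "w_unit", w_unit);
    G.plastic = as<bool>(gl["plastic"]);
    G.frozen = gl.containsElementNamed("frozen") ? as<bool>(gl["frozen"]) : false;
    G.active = false;
    if (G.kind == GRP_STDP) {
      G.eta = as<double>(gl["eta"]);
      G.alpha = as<double>(gl["alpha"]);
      G.A_minus = as<double>(gl["A_minus"]);
      G.w_min = as<double>(gl["w_min"]);
      G.w_max = as<double>(gl["w_max"]);
      double tp = as<double>(gl["tau_plus"]);
      double tm = num_or(gl, "tau_minus", 0.0);
      double wnd = 10.0 * std::max(tp, tm);
      G.Wsteps = (int)std::lround(wnd / dt);
      G.expP.resize(G.Wsteps + 1);
      G.expM.resize(G.Wsteps + 1);
      for (int k = 0; k <= G.Wsteps; ++k) {
        G.expP[k] = std::exp(-(k * dt) / tp);
        G.expM[k] = (tm > 0) ? std::exp(-(k * dt) / tm) : 0.0;
      }
      G.const_delay = 0; // pairing uses emission times; delays affect delivery only
    } else if (G.kind == GRP_TM) {
      G.U = as<double>(gl["U"]);
      G.tau_rec = as<double>(gl["tau_rec"]);
      G.tau_fac = as<double>(gl["tau_fac"]);
      G.tmx.assign(ne, 1.0);
      G.tmu.assign(ne, G.U);
      G.tm_last.assign(ne, -1);
      if (gl.containsElementNamed("tm_x")) {
        NumericVector x = gl["tm_x"], u = gl["tm_u"];
        for (int e = 0; e < ne; ++e) { G.tmx[e] = x[e]; G.tmu[e] = u[e]; }
      }
    }
  }
  const int L = max_d + 1;

  // --- parse populations ----------------------------------------------------
  for (int p = 0; p < npop; ++p) {
    List pl = pops_in[p];
    Pop &P = pops[p];
    P.kind = as<int>(pl["kind"]);
    P.n = as<int>(pl["n"]);
    P.space = as<int>(pl["space"]) - 1; // 0 in R means none
    NumericVector V = pl["V"], bs = pl["b_sfa"], rr = pl["refr_rem"], rd = pl["refr_dur"];
    P.V.assign(V.begin(), V.end());
    P.bsfa.assign(bs.begin(), bs.end());
    P.refr_rem.assign(rr.begin(), rr.end());
    P.refr_dur.assign(rd.begin(), rd.end());
    if (P.kind == POP_HAZARD) {
      P.c1 = num_or(pl, "c1", 0); P.c2 = num_or(pl, "c2", 0); P.c3 = num_or(pl, "c3", 0);
      P.tau_m = num_or(pl, "tau_m", 10); P.R_m = num_or(pl, "R_m", 0.5);
      P.I_e = num_or(pl, "I_e", 0);
      P.q_sfa = num_or(pl, "q_sfa", 0);
      P.tau_sfa_ms = num_or(pl, "tau_sfa_ms", 5000);
      P.b_max = num_or(pl, "b_max", 0);
      P.decay = std::exp(-dt / P.tau_m);
      P.bdecay = std::exp(-dt / P.tau_sfa_ms);
      P.drive_coef = (1.0 - P.decay) * P.R_m;
    } else if (P.kind == POP_LIF) {
      P.tau_m = num_or(pl, "tau_m", 20);
      P.v_rest = num_or(pl, "v_rest", -60);
      P.v_thresh = num_or(pl, "v_thresh", -20);
      P.refr_ms = num_or(pl, "refr_ms", 5);
      P.decay = std::exp(-dt / P.tau_m);
    }
    P.J.assign((size_t)L * P.n, 0.0);
    P.hist.assign((size_t)HIST_CAP * P.n, 0);
    P.hpos.assign(P.n, 0);
    P.hcnt.assign(P.n, 0);
    P.spike_ring.assign(L, std::vector<int>());
    P.pois_p.assign(P.n, 0.0);
    P.rng.seed((uint64_t)seed, (uint64_t)(p + 1));
  }

  for (int g = 0; g < ngrp; ++g) {
    Group &G = grps[g];
    build_csr(G.pre, pops[G.pre_pop].n, G.preOff, G.preIdx);
    build_csr(G.post, pops[G.post_pop].n, G.postOff, G.postIdx);
    if (G.kind == GRP_TM) G.tm_ring.assign(L, std::vector<int>());
  }

  // --- spaces ---------------------------------------------------------------
  std::vector<double> lock_nA(nspace, -4.0);
  std::vector<bool> neural(nspace, false);
  std::vector<std::vector<int> > space_pops(nspace);
  for (int s = 0; s < nspace; ++s) {
    List sl = spaces_in[s];
    lock_nA[s] = as<double>(sl["lock_nA"]);
    neural[s] = as<bool>(sl["neural"]);
    IntegerVector sp = sl["pops"];
    for (int i = 0; i < sp.size(); ++i) space_pops[s].push_back(sp[i] - 1);
  }

  // --- output buffers -------------------------------------------------------
  std::vector<int> out_pop, out_neuron;
  std::vector<double> out_time;
  std::vector<IntegerMatrix> counts(npop);
  for (int p = 0; p < npop; ++p) counts[p] = IntegerMatrix(pops[p].n, nphase);
  NumericVector phase_start(nphase), phase_end(nphase);

  int64_t t = 0; // global step counter

  for (int ph = 0; ph < nphase; ++ph) {
    List phl = phases_in[ph];
    double dur = as<double>(phl["duration_ms"]);
    int nsteps = (int)std::lround(dur / dt);
    bool record = as<bool>(phl["record"]);
    LogicalVector inhibited = phl["inhibited"]; // per space
    phase_start[ph] = t * dt;
    phase_end[ph] = (t + nsteps) * dt;

    // lock currents
    std::vector<double> I_inh(npop, 0.0);
    for (int s = 0; s < nspace; ++s)
      if (inhibited[s])
        for (size_t i = 0; i < space_pops[s].size(); ++i)
          I_inh[space_pops[s][i]] = lock_nA[s];
    for (int p = 0; p < npop; ++p) {
      Pop &P = pops[p];
      if (P.kind == POP_HAZARD)
        P.drive_const = P.drive_coef * (P.I_e + I_inh[p]);
    }

    // input rates
    List rates = phl["rates"]; // list parallel to pops (NULL or numeric)
    for (int p = 0; p < npop; ++p) {
      Pop &P = pops[p];
      if (P.kind != POP_POISSON) continue;
      if (rates.size() > p && !Rf_isNull(rates[p])) {
        NumericVector r = rates[p];
        for (int i = 0; i < P.n; ++i)
          P.pois_p[i] = 1.0 - std::exp(-r[i % r.size()] * dt_s);
      } else {
        std::fill(P.pois_p.begin(), P.pois_p.end(), 0.0);
      }
    }

    // plasticity gates: open iff plastic, not frozen, and every endpoint that
    // lies in a *neural* space is currently disinhibited
    for (int g = 0; g < ngrp; ++g) {
      Group &G = grps[g];
      if (G.kind != GRP_STDP || !G.plastic || G.frozen) { G.active = false; continue; }
      bool open = true;
      int sp1 = pops[G.pre_pop].space, sp2 = pops[G.post_pop].space;
      if (sp1 >= 0 && neural[sp1] && inhibited[sp1]) open = false;
      if (sp2 >= 0 && neural[sp2] && inhibited[sp2]) open = false;
      G.active = open;
    }

    for (int step = 0; step < nsteps; ++step, ++t) {
      const int slot = (int)(t % L);

      // ---- 1. short-term-depression arrivals ----
      for (int g = 0; g < ngrp; ++g) {
        Group &G = grps[g];
        if (G.kind != GRP_TM) continue;
        std::vector<int> &arr = G.tm_ring[slot];
        if (arr.empty()) continue;
        Pop &Q = pops[G.post_pop];
        for (size_t a = 0; a < arr.size(); ++a) {
          int e = arr[a];
          double x = G.tmx[e], u = G.tmu[e];
          if (G.tm_last[e] >= 0) {
            double gap = (t - G.tm_last[e]) * dt;
            x = 1.0 - (1.0 - x) * std::exp(-gap / G.tau_rec);
            u = G.U + (u - G.U) * std::exp(-gap / G.tau_fac);
          }
          double eff = u * x;
          int q = G.post[e];
          if (Q.refr_rem[q] <= 0)
            Q.V[q] += G.w_unit * G.w[e] * eff;
          G.tmx[e] = x * (1.0 - u);
          G.tmu[e] = u + G.U * (1.0 - u);
          G.tm_last[e] = t;
        }
        arr.clear();
      }

      // ---- 2. integrate and sample spikes ----
      for (int p = 0; p < npop; ++p) {
        Pop &P = pops[p];
        std::vector<int> &cur = P.cur;
        cur.clear();
        double *J = &P.J[(size_t)slot * P.n];
        int *cnt = &counts[p](0, ph);
        if (P.kind == POP_HAZARD) {
          const double decay = P.decay, bdec = P.bdecay, drive = P.drive_const;
          const double c1 = P.c1, c2 = P.c2, c3 = P.c3;
          for (int i = 0; i < P.n; ++i) {
            if (P.refr_rem[i] > 0) {
              P.refr_rem[i] -= dt;
              P.bsfa[i] *= bdec;
              J[i] = 0.0;
              continue;
            }
            double v = P.V[i] * decay + drive + J[i];
            J[i] = 0.0;
            double b = P.bsfa[i] * bdec;
            P.V[i] = v; P.bsfa[i] = b;
            double veff = v + b;
            // the hazard is <= 0 whenever veff <= 0 (c3 > 0, c1 >= 0), so
            // the exp and the uniform draw can be skipped outright
            if (veff <= 0.0) continue;
            double rho = c1 * veff;
            if (c2 != 0.0) rho += c2 * (std::exp(c3 * veff) - 1.0);
            if (rho <= 0.0) continue;
            double pr = 1.0 - std::exp(-rho * dt_s);
            if (P.rng.unif() < pr) {
              P.V[i] = 0.0;
              P.refr_rem[i] = P.refr_dur[i];
              double nb = b + P.q_sfa;
              P.bsfa[i] = nb > P.b_max ? P.b_max : nb;
              cur.push_back(i);
            }
          }
        } else if (P.kind == POP_POISSON) {
          for (int i = 0; i < P.n; ++i) {
            double pr = P.pois_p[i];
            if (pr > 0.0 && P.rng.unif() < pr) cur.push_back(i);
          }
        } else { // POP_LIF
          const double decay = P.decay, vr = P.v_rest;
          for (int i = 0; i < P.n; ++i) {
            if (P.refr_rem[i] > 0) {
              P.refr_rem[i] -= dt;
              P.V[i] = vr;
              J[i] = 0.0;
              continue;
            }
            double v = vr + (P.V[i] - vr) * decay + J[i];
            J[i] = 0.0;
            if (v >= P.v_thresh) {
              P.V[i] = vr;
              P.refr_rem[i] = P.refr_ms;
              cur.push_back(i);
            } else P.V[i] = v;
          }
        }
        // bookkeeping for this step's spikes
        std::vector<int> &ring = P.spike_ring[slot];
        ring.clear();
        for (size_t k = 0; k < cur.size(); ++k) {
          int i = cur[k];
          cnt[i]++;
          P.hist[(size_t)i * HIST_CAP + (P.hpos[i] % HIST_CAP)] = (int32_t)t;
          P.hpos[i]++;
          if (P.hcnt[i] < HIST_CAP) P.hcnt[i]++;
          ring.push_back(i);
          if (record) {
            out_pop.push_back(p + 1);
            out_neuron.push_back(i + 1);
            out_time.push_back(t * dt);
          }
        }
      }

      // ---- 3. delivery (weight read at emission) ----
      for (int g = 0; g < ngrp; ++g) {
        Group &G = grps[g];
        Pop &P = pops[G.pre_pop];
        if (P.cur.empty()) continue;
        if (G.kind == GRP_TM) {
          for (size_t k = 0; k < P.cur.size(); ++k) {
            int i = P.cur[k];
            for (int a = G.preOff[i]; a < G.preOff[i + 1]; ++a) {
              int e = G.preIdx[a];
              G.tm_ring[(slot + G.dstep[e]) % L].push_back(e);
            }
          }
        } else {
          Pop &Q = pops[G.post_pop];
          for (size_t k = 0; k < P.cur.size(); ++k) {
            int i = P.cur[k];
            for (int a = G.preOff[i]; a < G.preOff[i + 1]; ++a) {
              int e = G.preIdx[a];
              if (G.w[e] == 0.0) continue; // silent edge: nothing to deliver
              Q.J[(size_t)((slot + G.dstep[e]) % L) * Q.n + G.post[e]] += G.w_unit * G.w[e];
            }
          }
        }
      }

      // ---- 4. plasticity ----
      for (int g = 0; g < ngrp; ++g) {
        Group &G = grps[g];
        if (!G.active) continue;
        Pop &P = pops[G.pre_pop];
        Pop &Q = pops[G.post_pop];
        const double *expP = G.expP.data();
        const int W = G.Wsteps;

        // Pairing on emission times.  The dt >= 0 branch is applied once
        // per postsynaptic spike: the exponential term accumulates over
        // every presynaptic spike inside the pairing window while the
        // constant -A_minus offset counts once, so each postsynaptic
        // spike compares the presynaptic activity trace (rate x tau_plus)
        // against A_minus -- Hebbian potentiation above the presynaptic
        // rate A_minus / tau_plus, and active depression of edges whose
        // presynaptic partner is silent.  (Counting the offset per
        // pre/post spike pairing instead would accumulate a depression
        // that grows without bound with the presynaptic rate.)  The
        // dt < 0 branch is applied per presynaptic spike to the most
        // recent postsynaptic spike that had no presynaptic spike within
        // the window before it (so each such postsynaptic spike is
        // claimed at most once).

        // dt >= 0: triggered by this step's postsynaptic spikes
        for (size_t k = 0; k < Q.cur.size(); ++k) {
          int q = Q.cur[k];
          for (int a = G.postOff[q]; a < G.postOff[q + 1]; ++a) {
            int e = G.postIdx[a];
            int pn = G.pre[e];
            int m = P.hcnt[pn];
            const int32_t *h = &P.hist[(size_t)pn * HIST_CAP];
            int pos = P.hpos[pn];
            double acc = 0.0;
            for (int j = 1; j <= m; ++j) {
              int64_t kk = t - (int64_t)h[(pos - j) % HIST_CAP];
              if (kk > W) break;
              acc += expP[kk];
            }
            double nw = G.w[e] + G.eta * (acc - G.A_minus);
            if (nw < G.w_min) nw = G.w_min;
            if (nw > G.w_max) nw = G.w_max;
            G.w[e] = nw;
          }
        }

        // post-before-pre: triggered by this step's presynaptic spikes
        if (G.alpha != 0.0) {
          const double *expM = G.expM.data();
          for (size_t k = 0; k < P.cur.size(); ++k) {
            int pn = P.cur[k];
            // previous emission of this presynaptic neuron (the current
            // one is already in the history at position 1)
            int64_t s_prev = -1;
            if (P.hcnt[pn] >= 2)
              s_prev = P.hist[(size_t)pn * HIST_CAP + (P.hpos[pn] - 2) % HIST_CAP];
            for (int a = G.preOff[pn]; a < G.preOff[pn + 1]; ++a) {
              int e = G.preIdx[a];
              int q = G.post[e];
              if (Q.hcnt[q] == 0) continue;
              int64_t u = Q.hist[(size_t)q * HIST_CAP + (Q.hpos[q] - 1) % HIST_CAP];
              if (u == t && Q.hcnt[q] >= 2) // simultaneous post: other branch
                u = Q.hist[(size_t)q * HIST_CAP + (Q.hpos[q] - 2) % HIST_CAP];
              int64_t mm = t - u;
              if (mm < 1 || mm > W) continue;
              // the post spike is available only if it was not already
              // paired: not pot-paired (a pre within W before it) and not
              // dep-paired by an earlier pre since
              if (s_prev >= 0 && u - s_prev <= W) continue;
              double nw = G.w[e] + G.eta * G.alpha * (expM[mm] - G.A_minus);
              if (nw < G.w_min) nw = G.w_min;
              if (nw > G.w_max) nw = G.w_max;
              G.w[e] = nw;
            }
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  // --- collect outputs ------------------------------------------------------
  List states(npop);
  for (int p = 0; p < npop; ++p) {
    Pop &P = pops[p];
    states[p] = List::create(_["V"] = NumericVector(P.V.begin(), P.V.end()),
                             _["b_sfa"] = NumericVector(P.bsfa.begin(), P.bsfa.end()),
                             _["refr_rem"] = NumericVector(P.refr_rem.begin(), P.refr_rem.end()));
  }
  List weights(ngrp), tm_state(ngrp);
  for (int g = 0; g < ngrp; ++g) {
    Group &G = grps[g];
    weights[g] = NumericVector(G.w.begin(), G.w.end());
    if (G.kind == GRP_TM)
      tm_state[g] = List::create(_["x"] = NumericVector(G.tmx.begin(), G.tmx.end()),
                                 _["u"] = NumericVector(G.tmu.begin(), G.tmu.end()));
    else
      tm_state[g] = R_NilValue;
  }
  List counts_out(npop);
  for (int p = 0; p < npop; ++p) counts_out[p] = counts[p];

  return List::create(
      _["spikes"] = DataFrame::create(_["pop"] = IntegerVector(out_pop.begin(), out_pop.end()),
                                      _["neuron"] = IntegerVector(out_neuron.begin(), out_neuron.end()),
                                      _["time_ms"] = NumericVector(out_time.begin(), out_time.end())),
      _["counts"] = counts_out,
      _["states"] = states,
      _["weights"] = weights,
      _["tm_state"] = tm_state,
      _["phase_start"] = phase_start,
      _["phase_end"] = phase_end,
      _["t_end"] = (double)(t * dt));
}
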