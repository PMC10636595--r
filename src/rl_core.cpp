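// Simulation core: grid-world MDP, agent update rules and the three-phase
// protocol (training / pre-test / test), run per random seed. The per-step
// update rules mirror the plain-R reference implementations in R/agents.R;
// the two are bound together by replay tests (recorded transitions re-applied
// through the R rules must reproduce the final tables).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static const int N = 13, NC = 169;
static const int DX[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DY[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const double ALEN[8] = {1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2};

// ---------------------------------------------------------------- environment

struct Env {
  std::vector<int> acc, oneway;
  int shelter, threat;
  double reward;
  bool has_shelter;
};

static Env make_env(const List& m) {
  Env e;
  e.acc.assign(NC, 0);
  e.oneway.assign(NC * 8, 0);
  LogicalVector acc = m["accessible"];
  for (int i = 0; i < NC; i++) e.acc[i] = acc[i] ? 1 : 0;
  IntegerMatrix ow = m["oneway"];
  for (int k = 0; k < ow.nrow(); k++) e.oneway[(ow(k, 0) - 1) * 8 + (ow(k, 1) - 1)] = 1;
  IntegerVector shv = m["shelter"];
  e.shelter = (shv[0] == NA_INTEGER) ? -1 : shv[0] - 1;
  e.threat = as<int>(m["threat"]) - 1;
  e.reward = as<double>(m["reward"]);
  e.has_shelter = e.shelter >= 0;
  return e;
}

struct Step { int ns; double r; bool blocked; };

static Step env_step(const Env& E, int s, int a, double scale) {
  int c = s % N, r = s / N;
  int tc = c + DX[a], tr = r + DY[a];
  bool blocked = tc < 0 || tc >= N || tr < 0 || tr >= N;
  int to = blocked ? -1 : tr * N + tc;
  if (!blocked && !E.acc[to]) blocked = true;
  if (!blocked && E.oneway[s * 8 + a]) blocked = true;
  Step st;
  st.ns = blocked ? s : to;
  st.blocked = blocked;
  st.r = 0.0;
  if (E.has_shelter) {
    st.r = -scale * ALEN[a];
    if (!blocked && st.ns == E.shelter && s != E.shelter) st.r += E.reward;
  }
  return st;
}

// ---------------------------------------------------------------- eligibility

struct Trace {
  std::vector<double> e;
  std::vector<int> act;
  double cutoff;
  Trace(int n, double cut) : e(n, 0.0), cutoff(cut) {}
  void decay(double f) {
    size_t w = 0;
    for (size_t i = 0; i < act.size(); i++) {
      int idx = act[i];
      e[idx] *= f;
      if (e[idx] < cutoff) e[idx] = 0.0; else act[w++] = idx;
    }
    act.resize(w);
  }
  void add(int idx) {
    if (e[idx] == 0.0) act.push_back(idx);
    e[idx] += 1.0;
  }
};

struct HP {
  double gamma, lambda, alpha, scale, init_sd_q, init_sd_m, dual_threshold, cutoff;
  int buffer_n;
  bool sr_onpolicy;
};

static HP make_hp(const List& h) {
  HP hp;
  hp.gamma = as<double>(h["gamma"]);
  hp.lambda = as<double>(h["lambda"]);
  hp.alpha = as<double>(h["alpha"]);
  hp.scale = as<double>(h["step_scale"]);
  hp.init_sd_q = as<double>(h["init_sd_q"]);
  hp.init_sd_m = as<double>(h["init_sd_m"]);
  hp.dual_threshold = as<double>(h["dual_threshold"]);
  hp.cutoff = as<double>(h["trace_cutoff"]);
  hp.buffer_n = as<int>(h["buffer_n"]);
  hp.sr_onpolicy = as<bool>(h["sr_onpolicy"]);
  return hp;
}

static int pick_uniform(int k) {
  int i = (int)(unif_rand() * k);
  return i >= k ? k - 1 : i;
}

// greedy argmax with uniform tie-break over near-equal values
static int greedy_pick(const double* v, int n, double eps = 1e-9) {
  double best = v[0];
  for (int i = 1; i < n; i++) if (v[i] > best) best = v[i];
  int cand[64], nc = 0;
  for (int i = 0; i < n; i++) if (v[i] >= best - eps) cand[nc++] = i;
  return cand[pick_uniform(nc)];
}

// ---------------------------------------------------------------- tabular Q / SARSA

struct Tab {
  std::vector<double> Q;
  Trace tr;
  bool sarsa;
  Tab(const HP& hp, bool on_policy) : Q(NC * 8), tr(NC * 8, hp.cutoff), sarsa(on_policy) {
    for (auto& q : Q) q = norm_rand() * hp.init_sd_q;
  }
  void update(int s, int a, double r, int ns, int na, bool terminal, const HP& hp,
              bool blocked = false) {
    double boot;
    if (terminal) boot = 0.0;
    else if (sarsa) {
      if (na >= 0) boot = Q[ns * 8 + na];
      else { boot = 0.0; for (int b = 0; b < 8; b++) boot += Q[ns * 8 + b] / 8.0; }
    }
    else { boot = Q[ns * 8]; for (int b = 1; b < 8; b++) boot = std::max(boot, Q[ns * 8 + b]); }
    tr.decay(hp.lambda * hp.gamma);
    tr.add(s * 8 + a);
    double delta = r + hp.gamma * boot - Q[s * 8 + a];
    for (int idx : tr.act) Q[idx] += hp.alpha * delta * tr.e[idx];
    // a blocked attempt is updated once but is not credited with later
    // progress: the agent did not move, so the pair leaves the trace
    if (blocked) tr.e[s * 8 + a] = 0.0;
  }
  int greedy(int s) const { return greedy_pick(&Q[s * 8], 8); }
};

// ---------------------------------------------------------------- successor representation

struct SR {
  std::vector<double> M;  // (NC*8) x NC, row-major
  std::vector<double> R;
  Trace tr;
  std::vector<double> delta;
  SR(const HP& hp) : M((size_t)NC * 8 * NC), R(NC, 0.0), tr(NC * 8, hp.cutoff), delta(NC) {
    for (auto& m : M) m = norm_rand() * hp.init_sd_m;
  }
  // On-policy form: the expected next row is sampled by the action actually
  // taken at the successor state; na = -1 (episode truncation, where no next
  // action exists) and the uniform configuration both average over the eight
  // actions, the expectation under the random exploration policy.
  void update(int s, int a, double r, int ns, int na, bool terminal, const HP& hp,
              bool blocked = false) {
    size_t sa = (size_t)(s * 8 + a) * NC;
    for (int x = 0; x < NC; x++) delta[x] = -M[sa + x];
    if (terminal) {
      // episode ends: no future occupancy beyond the terminal state
    } else if (hp.sr_onpolicy && na >= 0) {
      const double* row = &M[(size_t)(ns * 8 + na) * NC];
      for (int x = 0; x < NC; x++) delta[x] += hp.gamma * row[x];
    } else {
      const double g8 = hp.gamma / 8.0;
      for (int b = 0; b < 8; b++) {
        const double* row = &M[(size_t)(ns * 8 + b) * NC];
        for (int x = 0; x < NC; x++) delta[x] += g8 * row[x];
      }
    }
    delta[ns] += 1.0;
    tr.decay(hp.lambda * hp.gamma);
    tr.add(s * 8 + a);
    for (int idx : tr.act) {
      double w = hp.alpha * tr.e[idx];
      double* row = &M[(size_t)idx * NC];
      for (int x = 0; x < NC; x++) row[x] += w * delta[x];
    }
    if (blocked) tr.e[s * 8 + a] = 0.0;
    R[ns] += hp.alpha * (r - R[ns]);
  }
  double value(int s, int a) const {
    const double* row = &M[(size_t)(s * 8 + a) * NC];
    double q = 0.0;
    for (int x = 0; x < NC; x++) q += row[x] * R[x];
    return q;
  }
  int greedy(int s) const {
    double v[8];
    for (int a = 0; a < 8; a++) v[a] = value(s, a);
    return greedy_pick(v, 8);
  }
};

// ---------------------------------------------------------------- tile coding

struct Tile {
  // 2x2 tiles on a 12x12 lattice (144) + 3x3 tiles on 11x11 (121), per action
  std::vector<double> w;  // 265*8
  std::vector<std::vector<int>> feats;  // per cell
  Tile() : w(265 * 8, 0.0), feats(NC) {
    for (int cell = 0; cell < NC; cell++) {
      int c = cell % N, r = cell / N;
      for (int tx = std::max(0, c - 1); tx <= std::min(11, c); tx++)
        for (int ty = std::max(0, r - 1); ty <= std::min(11, r); ty++)
          feats[cell].push_back(ty * 12 + tx);
      for (int tx = std::max(0, c - 2); tx <= std::min(10, c); tx++)
        for (int ty = std::max(0, r - 2); ty <= std::min(10, r); ty++)
          feats[cell].push_back(144 + ty * 11 + tx);
    }
  }
  double qhat(int s, int a) const {
    double q = 0.0;
    for (int t : feats[s]) q += w[t * 8 + a];
    return q;
  }
  void update(int s, int a, double r, int ns, bool terminal, const HP& hp) {
    double boot = 0.0;
    if (!terminal) {
      boot = qhat(ns, 0);
      for (int b = 1; b < 8; b++) boot = std::max(boot, qhat(ns, b));
    }
    double delta = r + hp.gamma * boot - qhat(s, a);
    // learning rate shared across the active (overlapping) tiles
    double step = hp.alpha / (double)feats[s].size();
    for (int t : feats[s]) w[t * 8 + a] += step * delta;
  }
  int greedy(int s) const {
    double v[8];
    for (int a = 0; a < 8; a++) v[a] = qhat(s, a);
    return greedy_pick(v, 8);
  }
};

// ---------------------------------------------------------------- model-based

struct MB {
  bool gradual;
  int bufN;
  std::vector<uint8_t> node;
  std::vector<int8_t> estat;           // immediate: -1 unknown, 1 open, 0 deleted
  std::vector<uint8_t> ering, ecnt, epos, esum;  // gradual edge buffers
  std::vector<double> nrew;            // immediate node label
  std::vector<double> rring;           // gradual reward buffers
  std::vector<uint8_t> rcnt, rpos;
  MB(bool grad, int n)
      : gradual(grad), bufN(n), node(NC, 0), estat(NC * 8, -1),
        ering(grad ? NC * 8 * n : 0, 0), ecnt(NC * 8, 0), epos(NC * 8, 0), esum(NC * 8, 0),
        nrew(NC, 0.0), rring(grad ? NC * n : 0, 0.0), rcnt(NC, 0), rpos(NC, 0) {}

  void push_edge(int slot, int open) {
    if (!gradual) { estat[slot] = open; return; }
    uint8_t* ring = &ering[(size_t)slot * bufN];
    if (ecnt[slot] < bufN) ecnt[slot]++;
    else esum[slot] -= ring[epos[slot]];
    ring[epos[slot]] = (uint8_t)open;
    esum[slot] += open;
    epos[slot] = (epos[slot] + 1) % bufN;
  }
  bool edge_open(int s, int a) const {
    int slot = s * 8 + a;
    if (!gradual) return estat[slot] == 1;
    return ecnt[slot] > 0 && 2 * (int)esum[slot] > (int)ecnt[slot];
  }
  void push_reward(int cell, double r) {
    if (!gradual) { nrew[cell] = r; return; }
    double* ring = &rring[(size_t)cell * bufN];
    rcnt[cell] = std::min<int>(rcnt[cell] + 1, bufN);
    ring[rpos[cell]] = r;
    rpos[cell] = (rpos[cell] + 1) % bufN;
  }
  double node_value(int cell) const {
    if (!gradual) return nrew[cell];
    if (rcnt[cell] == 0) return 0.0;
    double m = 0.0;
    const double* ring = &rring[(size_t)cell * bufN];
    for (int i = 0; i < rcnt[cell]; i++) m += ring[i];
    return m / rcnt[cell];
  }
  // observe transition attempt s --a--> (target), open = !blocked;
  // entered = agent arrived at a (possibly new) cell
  void observe(int s, int a, bool blocked, double bonus, int ns) {
    node[s] = 1;
    int c = s % N, r = s / N;
    int tc = c + DX[a], tr = r + DY[a];
    if (tc >= 0 && tc < N && tr >= 0 && tr < N) {
      int t = tr * N + tc;
      push_edge(s * 8 + a, blocked ? 0 : 1);
      push_edge(t * 8 + (a + 4) % 8, blocked ? 0 : 1);  // undirected graph
    }
    if (!blocked) {
      node[ns] = 1;
      push_reward(ns, bonus);
    }
  }
  // Dijkstra over known nodes / open edges; dist from a source
  void dijkstra(int src, std::vector<double>& dist) const {
    dist.assign(NC, 1e300);
    if (!node[src]) return;
    typedef std::pair<double, int> P;
    std::priority_queue<P, std::vector<P>, std::greater<P>> pq;
    dist[src] = 0.0;
    pq.push(P(0.0, src));
    while (!pq.empty()) {
      P top = pq.top(); pq.pop();
      if (top.first > dist[top.second] + 1e-12) continue;
      int u = top.second;
      for (int a = 0; a < 8; a++) {
        if (!edge_open(u, a)) continue;
        int c = u % N, r = u / N;
        int tc = c + DX[a], tr = r + DY[a];
        if (tc < 0 || tc >= N || tr < 0 || tr >= N) continue;
        int v = tr * N + tc;
        if (!node[v]) continue;
        double nd = top.first + ALEN[a];
        if (nd < dist[v] - 1e-12) { dist[v] = nd; pq.push(P(nd, v)); }
      }
    }
  }
  // first action of a shortest route to the best-reward node; -1 if no plan
  int plan_action(int s) {
    std::vector<double> dsrc;
    dijkstra(s, dsrc);
    double best = 0.0;
    for (int x = 0; x < NC; x++)
      if (node[x] && dsrc[x] < 1e299) best = std::max(best, node_value(x));
    if (best <= 0.0) return -1;
    int goal = -1;
    double gd = 1e300;
    for (int x = 0; x < NC; x++)
      if (node[x] && dsrc[x] < 1e299 && node_value(x) >= best - 1e-9 && dsrc[x] < gd) {
        gd = dsrc[x]; goal = x;
      }
    if (goal == s) return -1;  // already at goal
    std::vector<double> dg;
    dijkstra(goal, dg);
    int cand[8], nc = 0;
    for (int a = 0; a < 8; a++) {
      if (!edge_open(s, a)) continue;
      int c = s % N, r = s / N;
      int tc = c + DX[a], tr = r + DY[a];
      if (tc < 0 || tc >= N || tr < 0 || tr >= N) continue;
      int v = tr * N + tc;
      if (!node[v] || dg[v] > 1e299) continue;
      if (std::abs(ALEN[a] + dg[v] - dg[s]) < 1e-9) cand[nc++] = a;
    }
    if (nc == 0) return -1;
    return cand[pick_uniform(nc)];
  }
};

// ---------------------------------------------------------------- hierarchical state space

struct HSS {
  std::vector<double> Q;
  Trace tr;
  std::vector<int> region;         // per cell, 0-based, -1 off-arena
  std::vector<int> ra_from, ra_to; // region-action pairs
  int ra_idx[10][10];
  std::vector<double> cdist;
  std::vector<int> anchors;        // per region, cell ids
  int shelter_region;
  bool sarsa;
  int cur_region;
  int pend_sa; double accum; bool has_pend;
  std::vector<int> line; size_t line_pos;  // test-time low-level execution

  HSS(const List& reg, const HP& hp, bool on_policy)
      : Q(0), tr(0, hp.cutoff), sarsa(on_policy), cur_region(-1),
        pend_sa(-1), accum(0.0), has_pend(false), line_pos(0) {
    IntegerVector assign = reg["assignment"];
    region.assign(NC, -1);
    for (int i = 0; i < NC; i++) region[i] = (assign[i] == NA_INTEGER) ? -1 : assign[i] - 1;
    IntegerMatrix acts = reg["actions"];
    NumericMatrix cent = reg["centroids"];
    IntegerVector anc = reg["anchors"];
    for (int i = 0; i < anc.size(); i++) anchors.push_back(anc[i] - 1);  // to 0-based
    for (int i = 0; i < 10; i++) for (int j = 0; j < 10; j++) ra_idx[i][j] = -1;
    int nra = acts.nrow();
    Q.resize(nra);
    tr = Trace(nra, hp.cutoff);
    for (int k = 0; k < nra; k++) {
      int f = acts(k, 0) - 1, t = acts(k, 1) - 1;
      ra_from.push_back(f); ra_to.push_back(t);
      ra_idx[f][t] = k;
      double dc = cent(f, 0) - cent(t, 0), dr = cent(f, 1) - cent(t, 1);
      cdist.push_back(std::sqrt(dc * dc + dr * dr));
    }
    for (auto& q : Q) q = norm_rand() * hp.init_sd_q;
    shelter_region = as<int>(reg["shelter_region"]) - 1;
  }

  double boot_max(int j) const {
    double b = -1e300; bool any = false;
    for (int k = 0; k < 10; k++)
      if (ra_idx[j][k] >= 0) { b = std::max(b, Q[ra_idx[j][k]]); any = true; }
    return any ? b : 0.0;
  }
  // Region actions are temporally extended: discounting (and trace decay) use
  // gamma^(centroid distance), the action's effective duration in grid steps,
  // matching the centroid-distance step penalty.
  void apply(int sa, double r, double boot, const HP& hp) {
    double gam_eff = std::pow(hp.gamma, cdist[sa]);
    tr.decay(hp.lambda * gam_eff);
    tr.add(sa);
    double delta = r + gam_eff * boot - Q[sa];
    for (int idx : tr.act) Q[idx] += hp.alpha * delta * tr.e[idx];
  }
  // Called after every grid transition when learning is on. A region action
  // (i -> j) is scored by the shelter-cell entry bonus accumulated while the
  // agent is inside j, so its update is applied at the next crossing, when
  // that return is known; the step penalty is the centroid distance.
  void notice(int ns, double bonus, bool has_shelter, bool terminal, const HP& hp) {
    accum += bonus;
    int j = region[ns];
    if (terminal) {
      // shelter reached: flush the pending region action with its accumulated
      // return and a zero bootstrap, then close the episode
      if (has_pend) {
        double r = has_shelter ? accum - hp.scale * cdist[pend_sa] : 0.0;
        apply(pend_sa, r, 0.0, hp);
      }
      has_pend = false; accum = 0.0; cur_region = j;
      tr.decay(0.0);
      return;
    }
    if (j == cur_region || j < 0) return;
    int sa_new = (cur_region >= 0) ? ra_idx[cur_region][j] : -1;
    if (has_pend) {
      double r = has_shelter ? accum - hp.scale * cdist[pend_sa] : 0.0;
      if (sarsa) {
        if (sa_new >= 0) apply(pend_sa, r, Q[sa_new], hp);
        // crossing without a defined on-policy next action: drop pending
      } else {
        apply(pend_sa, r, boot_max(cur_region), hp);
      }
    }
    has_pend = sa_new >= 0;
    pend_sa = sa_new;
    accum = 0.0;
    cur_region = j;
  }
  int greedy_action(int i) const {
    double v[10]; int ids[10]; int n = 0;
    for (int k = 0; k < 10; k++)
      if (ra_idx[i][k] >= 0) { v[n] = Q[ra_idx[i][k]]; ids[n] = ra_idx[i][k]; n++; }
    if (n == 0) return -1;
    return ids[greedy_pick(v, n)];
  }
  void reset_phase(int s) {
    cur_region = region[s];
    line.clear(); line_pos = 0;
    has_pend = false;  // a pending region update does not survive teleports
    accum = 0.0;
  }
};

// Bresenham 8-connected line, cells from -> to inclusive
static std::vector<int> raster_line(int from, int to) {
  int x0 = from % N, y0 = from / N, x1 = to % N, y1 = to / N;
  int dx = std::abs(x1 - x0), sx = x0 < x1 ? 1 : -1;
  int dy = -std::abs(y1 - y0), sy = y0 < y1 ? 1 : -1;
  int err = dx + dy;
  std::vector<int> path;
  path.push_back(y0 * N + x0);
  while (!(x0 == x1 && y0 == y1)) {
    int e2 = 2 * err;
    if (e2 >= dy) { err += dy; x0 += sx; }
    if (e2 <= dx) { err += dx; y0 += sy; }
    path.push_back(y0 * N + x0);
  }
  return path;
}

static int action_between(int from, int to) {
  int dc = to % N - from % N, dr = to / N - from / N;
  for (int a = 0; a < 8; a++) if (DX[a] == dc && DY[a] == dr) return a;
  return -1;
}

// wall sliding for the straight-line controller: when the intended step is
// blocked, try the two 45-degree neighbours of the intended action and take
// the one that still approaches the target; -1 when neither does
static int slide_action(const Env& E, int s, int a, int target) {
  double tx = target % N, ty = target / N;
  double cx = s % N, cy = s / N;
  double d0 = (cx - tx) * (cx - tx) + (cy - ty) * (cy - ty);
  int best = -1; double bestd = d0;
  for (int off = -1; off <= 1; off += 2) {
    int b = (a + off + 8) % 8;
    Step st = env_step(E, s, b, 0.0);
    if (st.blocked) continue;
    double nx = st.ns % N, ny = st.ns / N;
    double d = (nx - tx) * (nx - tx) + (ny - ty) * (ny - ty);
    if (d < bestd - 1e-9) { bestd = d; best = b; }
  }
  return best;
}

// ---------------------------------------------------------------- protocol driver

struct Agents {
  int algo;
  Tab* tab = nullptr;
  SR* sr = nullptr;
  Tile* tile = nullptr;
  MB* mb = nullptr;
  HSS* hss = nullptr;
  Tab* dual_tab = nullptr;
  MB* dual_mb = nullptr;
  ~Agents() { delete tab; delete sr; delete tile; delete mb; delete hss; delete dual_tab; delete dual_mb; }
};

// learning update shared by all phases; SARSA-style agents buffer one step
struct Pending { int s, a, ns; double r; bool blocked = false; bool have = false; };

// at episode truncation a pending on-policy step is closed with the uniform
// expectation over next actions (the random exploration policy's expectation)
static void flush_pending(Agents& A, Pending& pend, const HP& hp) {
  if (!pend.have) return;
  if (A.algo == 2) A.tab->update(pend.s, pend.a, pend.r, pend.ns, -1, false, hp, pend.blocked);
  if (A.algo == 3) A.sr->update(pend.s, pend.a, pend.r, pend.ns, -1, false, hp, pend.blocked);
  pend.have = false;
}

// terminal marks a transition entering the absorbing shelter state: the
// bootstrap is zero, pending on-policy updates are flushed, and the caller
// clears eligibility traces afterwards.
static void learn_step(Agents& A, Pending& pend, int s, int a, double r, int ns,
                       double bonus, bool has_shelter, bool terminal, const HP& hp,
                       bool blocked = false) {
  switch (A.algo) {
    case 1: A.tab->update(s, a, r, ns, 0, terminal, hp, blocked); break;
    case 2:
      if (pend.have) A.tab->update(pend.s, pend.a, pend.r, pend.ns, a, false, hp, pend.blocked);
      if (terminal) { A.tab->update(s, a, r, ns, 0, true, hp, blocked); pend.have = false; }
      else { pend.s = s; pend.a = a; pend.r = r; pend.ns = ns; pend.blocked = blocked; pend.have = true; }
      break;
    case 3:
      if (pend.have) A.sr->update(pend.s, pend.a, pend.r, pend.ns, a, false, hp, pend.blocked);
      if (terminal) { A.sr->update(s, a, r, ns, 0, true, hp, blocked); pend.have = false; }
      else { pend.s = s; pend.a = a; pend.r = r; pend.ns = ns; pend.blocked = blocked; pend.have = true; }
      break;
    case 4: A.tile->update(s, a, r, ns, terminal, hp); break;
    case 5: case 6: break;  // model-based observe handled separately
    case 7: case 8: A.hss->notice(ns, bonus, has_shelter, terminal, hp); break;
    case 9: A.dual_tab->update(s, a, r, ns, 0, terminal, hp, blocked); break;
  }
  if (terminal) {
    if (A.tab) A.tab->tr.decay(0.0);
    if (A.sr) A.sr->tr.decay(0.0);
    if (A.dual_tab) A.dual_tab->tr.decay(0.0);
  }
}

static int greedy_action(Agents& A, int s, const HP& hp) {
  switch (A.algo) {
    case 1: case 2: return A.tab->greedy(s);
    case 3: return A.sr->greedy(s);
    case 4: return A.tile->greedy(s);
    case 5: case 6: return A.mb->plan_action(s);
    case 9: {
      int a = A.dual_tab->greedy(s);
      if (A.dual_tab->Q[s * 8 + a] > hp.dual_threshold) return a;
      return A.dual_mb->plan_action(s);
    }
  }
  return -1;
}

// greedy rollout (learning off) used for calibration checkpoints
static bool eval_rollout(Agents& A, const Env& E, const HP& hp, int cap) {
  if (!E.has_shelter) return false;
  int s = E.threat;
  if (A.algo == 7 || A.algo == 8) {
    HSS& H = *A.hss;
    int cur = H.region[s];
    std::vector<int> line; size_t lp = 0;
    for (int t = 0; t < cap; t++) {
      if (lp + 1 >= line.size()) {
        int sa = H.greedy_action(cur);
        if (sa < 0) return false;
        line = raster_line(s, H.anchors[H.ra_to[sa]]);
        lp = 0;
        if (line.size() < 2) return false;
      }
      int a = action_between(line[lp], line[lp + 1]);
      Step st = env_step(E, s, a, hp.scale);
      if (st.blocked) {
        int target = line.back();
        int b = slide_action(E, s, a, target);
        if (b >= 0) {
          st = env_step(E, s, b, hp.scale);
          s = st.ns;
          line = raster_line(s, target);
          lp = 0;
        } else { line.clear(); lp = 0; }
      } else { s = st.ns; lp++; }
      cur = H.region[s];
      if (s == E.shelter) return true;
    }
    return false;
  }
  for (int t = 0; t < cap; t++) {
    int a = greedy_action(A, s, hp);
    if (a < 0) return false;
    Step st = env_step(E, s, a, hp.scale);
    s = st.ns;
    if (s == E.shelter) return true;
  }
  return false;
}

// [[Rcpp::export]]
List cpp_simulate(List map_train, List map_test, List regions, int algo, List hp_list,
                  List practice, int n_train, int n_trials, IntegerVector eval_at,
                  bool record, bool return_agent, int test_cap = 100,
                  int pretest_cap = 10000, bool learn_at_test = false,
                  int episode_cap = 200) {
  RNGScope scope;
  Env Etr = make_env(map_train), Ete = make_env(map_test);
  HP hp = make_hp(hp_list);

  Agents A; A.algo = algo;
  switch (algo) {
    case 1: A.tab = new Tab(hp, false); break;
    case 2: A.tab = new Tab(hp, true); break;
    case 3: A.sr = new SR(hp); break;
    case 4: A.tile = new Tile(); break;
    case 5: A.mb = new MB(false, hp.buffer_n); break;
    case 6: A.mb = new MB(true, hp.buffer_n); break;
    case 7: A.hss = new HSS(regions, hp, false); break;
    case 8: A.hss = new HSS(regions, hp, true); break;
    case 9: A.dual_tab = new Tab(hp, false); A.dual_mb = new MB(false, hp.buffer_n); break;
    default: stop("unknown algorithm code");
  }

  List init_snapshot;
  if (record) {
    if (A.tab) init_snapshot["Q"] = NumericVector(A.tab->Q.begin(), A.tab->Q.end());
    if (A.sr) {
      init_snapshot["M"] = NumericVector(A.sr->M.begin(), A.sr->M.end());
      init_snapshot["R"] = NumericVector(A.sr->R.begin(), A.sr->R.end());
    }
    if (A.tile) init_snapshot["w"] = NumericVector(A.tile->w.begin(), A.tile->w.end());
    if (A.hss) init_snapshot["Q"] = NumericVector(A.hss->Q.begin(), A.hss->Q.end());
    if (A.dual_tab) init_snapshot["Q"] = NumericVector(A.dual_tab->Q.begin(), A.dual_tab->Q.end());
  }

  // practice spec
  IntegerVector pstarts;
  List pseqs;
  double pprob = 0.0;
  if (practice.size() > 0) {
    pstarts = practice["starts"];
    pseqs = practice["seqs"];
    pprob = as<double>(practice["prob"]);
  }

  Pending pend;
  std::vector<double> rec;
  if (record) rec.reserve((size_t)n_train * 6);

  // --- training phase: episodes from uniform random drop-in locations ------
  // An episode ends on shelter entry (absorbing reward state) or at the
  // episode cap; the total step budget n_train is preserved across episodes.
  std::vector<int> acc_cells;
  for (int i = 0; i < NC; i++) if (Etr.acc[i]) acc_cells.push_back(i);
  int s = acc_cells[pick_uniform((int)acc_cells.size())];
  if (A.mb) A.mb->node[s] = 1;
  if (A.dual_mb) A.dual_mb->node[s] = 1;
  if (A.hss) A.hss->reset_phase(s);

  LogicalVector evals(eval_at.size());
  int eval_i = 0;
  int pr_seq = -1, pr_pos = 0, ep_steps = 0;

  for (int t = 1; t <= n_train; t++) {
    int a;
    if (pr_seq >= 0) {
      IntegerVector sq = pseqs[pr_seq];
      a = sq[pr_pos] - 1;
    } else {
      a = pick_uniform(8);
    }
    Step st = env_step(Etr, s, a, hp.scale);
    bool terminal = !st.blocked && Etr.has_shelter && st.ns == Etr.shelter && s != Etr.shelter;
    double bonus = terminal ? Etr.reward : 0.0;
    if (A.mb) A.mb->observe(s, a, st.blocked, bonus, st.ns);
    if (A.dual_mb) A.dual_mb->observe(s, a, st.blocked, bonus, st.ns);
    learn_step(A, pend, s, a, st.r, st.ns, bonus, Etr.has_shelter, terminal, hp, st.blocked);
    if (record) {
      rec.push_back(s + 1); rec.push_back(a + 1); rec.push_back(st.r);
      rec.push_back(st.ns + 1); rec.push_back(st.blocked ? 1 : 0);
      rec.push_back(terminal ? 1 : 0);  // episode event: 1 terminal, 2 truncated
    }
    // practice-run bookkeeping; a scripted run that completes uninterrupted
    // closes the episode (an interrupted one leaves the agent wandering)
    bool run_done = false;
    if (pr_seq >= 0) {
      pr_pos++;
      IntegerVector sq = pseqs[pr_seq];
      if (st.blocked || pr_pos >= sq.size()) {
        run_done = !st.blocked && pr_pos >= sq.size();
        pr_seq = -1; pr_pos = 0;
      }
    }
    bool entered = st.ns != s;
    s = st.ns;
    ep_steps++;
    if (terminal || run_done || ep_steps >= episode_cap) {
      // new episode: fresh uniform drop-in; traces/pendings do not carry over
      if (!terminal) {
        flush_pending(A, pend, hp);
        if (record) rec.back() = 2;  // mark the truncation boundary
      }
      s = acc_cells[pick_uniform((int)acc_cells.size())];
      ep_steps = 0;
      pr_seq = -1; pr_pos = 0;
      pend.have = false;
      if (A.tab) A.tab->tr.decay(0.0);
      if (A.sr) A.sr->tr.decay(0.0);
      if (A.dual_tab) A.dual_tab->tr.decay(0.0);
      if (A.mb) A.mb->node[s] = 1;
      if (A.dual_mb) A.dual_mb->node[s] = 1;
      if (A.hss) A.hss->reset_phase(s);
    } else if (pr_seq < 0 && entered && pprob > 0.0) {
      std::vector<int> hits;
      for (int k = 0; k < pstarts.size(); k++) if (pstarts[k] - 1 == s) hits.push_back(k);
      if (!hits.empty() && unif_rand() < pprob)
        pr_seq = hits[pick_uniform((int)hits.size())], pr_pos = 0;
    }
    while (eval_i < eval_at.size() && t == eval_at[eval_i]) {
      evals[eval_i] = eval_rollout(A, Etr, hp, test_cap);
      eval_i++;
    }
  }

  // --- trials: pre-test + test ---------------------------------------------
  List trials(n_trials);
  IntegerVector pretest_steps(n_trials);
  LogicalVector pretest_capped(n_trials);
  for (int trial = 0; trial < n_trials; trial++) {
    if (!Ete.has_shelter) stop("test map must have a shelter");
    s = Ete.shelter;
    pend.have = false;  // pending SARSA step does not survive the teleport
    // starting inside the shelter is an observation of its reward
    if (A.mb) { A.mb->node[s] = 1; A.mb->push_reward(s, Ete.reward); }
    if (A.dual_mb) { A.dual_mb->node[s] = 1; A.dual_mb->push_reward(s, Ete.reward); }
    if (A.hss) A.hss->reset_phase(s);
    int steps = 0;
    while (s != Ete.threat && steps < pretest_cap) {
      int a = pick_uniform(8);
      Step st = env_step(Ete, s, a, hp.scale);
      bool terminal = !st.blocked && st.ns == Ete.shelter && s != Ete.shelter;
      double bonus = terminal ? Ete.reward : 0.0;
      if (A.mb) A.mb->observe(s, a, st.blocked, bonus, st.ns);
      if (A.dual_mb) A.dual_mb->observe(s, a, st.blocked, bonus, st.ns);
      learn_step(A, pend, s, a, st.r, st.ns, bonus, Ete.has_shelter, terminal, hp, st.blocked);
      s = st.ns;
      steps++;
    }
    pretest_steps[trial] = steps;
    pretest_capped[trial] = s != Ete.threat;
    if (pretest_capped[trial]) { trials[trial] = IntegerVector(0); continue; }

    // test phase: frozen learned policy from the threat cell
    std::vector<int> path;
    path.push_back(s + 1);
    if (A.hss) { A.hss->reset_phase(s); }
    for (int t = 0; t < test_cap && s != Ete.shelter; t++) {
      int a;
      if (A.hss) {
        HSS& H = *A.hss;
        if (H.line_pos + 1 >= H.line.size()) {
          int sa = H.greedy_action(H.region[s]);
          if (sa < 0) { path.push_back(s + 1); continue; }
          H.line = raster_line(s, H.anchors[H.ra_to[sa]]);
          H.line_pos = 0;
          if (H.line.size() < 2) { path.push_back(s + 1); continue; }
        }
        a = action_between(H.line[H.line_pos], H.line[H.line_pos + 1]);
      } else {
        a = greedy_action(A, s, hp);
      }
      if (a < 0) { path.push_back(s + 1); continue; }  // no plan: stay
      Step st = env_step(Ete, s, a, hp.scale);
      if (A.hss && st.blocked && A.hss->line.size() > 0) {
        int target = A.hss->line.back();
        int b = slide_action(Ete, s, a, target);
        if (b >= 0) {
          a = b;
          st = env_step(Ete, s, a, hp.scale);
          A.hss->line = raster_line(st.ns, target);
          A.hss->line_pos = 0;
        }
      }
      {
        bool terminal = !st.blocked && st.ns == Ete.shelter && s != Ete.shelter;
        double bonus = terminal ? Ete.reward : 0.0;
        // the model-based world model updates immediately at every visit --
        // that is the agent's defining property and part of its action
        // selection; value tables follow the frozen learned policy unless
        // learning at test is requested
        if (A.mb) A.mb->observe(s, a, st.blocked, bonus, st.ns);
        if (A.dual_mb) A.dual_mb->observe(s, a, st.blocked, bonus, st.ns);
        if (learn_at_test)
          learn_step(A, pend, s, a, st.r, st.ns, bonus, Ete.has_shelter, terminal, hp, st.blocked);
      }
      if (A.hss) {
        if (st.blocked) { A.hss->line.clear(); A.hss->line_pos = 0; }
        else if (A.hss->line_pos + 1 < A.hss->line.size() &&
                 A.hss->line[A.hss->line_pos + 1] == st.ns) A.hss->line_pos++;
      }
      s = st.ns;
      path.push_back(s + 1);
    }
    trials[trial] = IntegerVector(path.begin(), path.end());
  }

  // --- outputs --------------------------------------------------------------
  List out;
  out["trials"] = trials;
  out["evals"] = evals;
  out["pretest_steps"] = pretest_steps;
  out["pretest_capped"] = pretest_capped;
  if (record) {
    NumericMatrix tm((int)(rec.size() / 6), 6);
    for (size_t i = 0; i < rec.size() / 6; i++)
      for (int j = 0; j < 6; j++) tm((int)i, j) = rec[i * 6 + j];
    colnames(tm) = CharacterVector::create("s", "a", "r", "ns", "blocked", "event");
    out["transitions"] = tm;
    out["init"] = init_snapshot;
  }
  if (return_agent) {
    List snap;
    if (A.tab) snap["Q"] = NumericVector(A.tab->Q.begin(), A.tab->Q.end());
    if (A.sr) {
      snap["M"] = NumericVector(A.sr->M.begin(), A.sr->M.end());
      snap["R"] = NumericVector(A.sr->R.begin(), A.sr->R.end());
    }
    if (A.tile) snap["w"] = NumericVector(A.tile->w.begin(), A.tile->w.end());
    if (A.mb) {
      snap["node"] = IntegerVector(A.mb->node.begin(), A.mb->node.end());
      IntegerVector eop(NC * 8);
      for (int i = 0; i < NC * 8; i++) {
        if (A.mb->gradual) eop[i] = A.mb->ecnt[i] == 0 ? -1 : (2 * (int)A.mb->esum[i] > (int)A.mb->ecnt[i] ? 1 : 0);
        else eop[i] = A.mb->estat[i];
      }
      snap["edge_open"] = eop;
      NumericVector nv(NC);
      for (int i = 0; i < NC; i++) nv[i] = A.mb->node_value(i);
      snap["node_value"] = nv;
    }
    if (A.hss) snap["Q"] = NumericVector(A.hss->Q.begin(), A.hss->Q.end());
    if (A.dual_tab) {
      snap["Q"] = NumericVector(A.dual_tab->Q.begin(), A.dual_tab->Q.end());
      IntegerVector nd(A.dual_mb->node.begin(), A.dual_mb->node.end());
      snap["node"] = nd;
    }
    out["agent"] = snap;
  }
  return out;
}
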