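// Radial engine: per-link radius-limited subsystems (Euclidean network
// distance, continuous or discrete space), angular geodesics over link-end
// states, convex-hull reach statistics, and the angular betweenness family.
// Geometry is polyline-exact; all distances in meters, angles in degrees.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double TOL_ARC = 1e-9;   // arc-position tolerance (m)
static const double TOL_TH = 1e-7;    // angular-cost tie tolerance (deg)
static const double TOL_LEN = 1e-5;   // length tie tolerance (m)

struct Net {
  int nL, nN;
  std::vector<std::vector<double> > px, py, arc; // per-link polyline + cum arc
  std::vector<int> na, nb;
  std::vector<double> len, w;
  std::vector<int> degree;
  // node -> incident (link, end): end 0 = a, 1 = b
  std::vector<std::vector<std::pair<int,int> > > inc;
};

static Net make_net(const List& nl) {
  Net net;
  NumericMatrix coords = nl["coords"];
  IntegerVector off = nl["off"];
  IntegerVector na = nl["node_a"], nb = nl["node_b"];
  NumericVector w = nl["weight"];
  IntegerVector deg = nl["node_degree"];
  net.nL = na.size();
  net.nN = as<int>(nl["n_nodes"]);
  net.px.resize(net.nL); net.py.resize(net.nL); net.arc.resize(net.nL);
  net.na.resize(net.nL); net.nb.resize(net.nL);
  net.len.resize(net.nL); net.w.resize(net.nL);
  net.degree.assign(deg.begin(), deg.end());
  net.inc.resize(net.nN);
  for (int e = 0; e < net.nL; ++e) {
    int s = off[e], t = off[e + 1];
    int m = t - s;
    net.px[e].resize(m); net.py[e].resize(m); net.arc[e].resize(m);
    double cum = 0;
    for (int i = 0; i < m; ++i) {
      net.px[e][i] = coords(s + i, 0);
      net.py[e][i] = coords(s + i, 1);
      if (i > 0) cum += std::hypot(net.px[e][i] - net.px[e][i-1],
                                   net.py[e][i] - net.py[e][i-1]);
      net.arc[e][i] = cum;
    }
    net.na[e] = na[e]; net.nb[e] = nb[e];
    net.len[e] = cum;  net.w[e] = w[e];
    net.inc[na[e]].push_back(std::make_pair(e, 0));
    net.inc[nb[e]].push_back(std::make_pair(e, 1));
  }
  return net;
}

static double angle_deg(double ux, double uy, double vx, double vy) {
  // atan2 form: well-conditioned for near-collinear and near-opposite vectors
  double cross = ux * vy - uy * vx;
  double dot = ux * vx + uy * vy;
  if (cross == 0 && dot == 0) return 0;
  return std::atan2(std::fabs(cross), dot) * 180.0 / M_PI;
}

// sum of deflection angles at interior vertices with arc strictly in (s, t)
static double internal_cost(const Net& net, int e, double s, double t) {
  if (t < s) std::swap(s, t);
  const std::vector<double>& arc = net.arc[e];
  int m = arc.size();
  double tot = 0;
  for (int i = 1; i + 1 < m; ++i) {
    if (arc[i] > s + TOL_ARC && arc[i] < t - TOL_ARC) {
      tot += angle_deg(net.px[e][i] - net.px[e][i-1], net.py[e][i] - net.py[e][i-1],
                       net.px[e][i+1] - net.px[e][i], net.py[e][i+1] - net.py[e][i]);
    }
  }
  return tot;
}

static void point_at(const Net& net, int e, double s, double& x, double& y) {
  const std::vector<double>& arc = net.arc[e];
  int m = arc.size();
  if (s <= 0) { x = net.px[e][0]; y = net.py[e][0]; return; }
  if (s >= arc[m-1]) { x = net.px[e][m-1]; y = net.py[e][m-1]; return; }
  int i = int(std::upper_bound(arc.begin(), arc.end(), s) - arc.begin());
  if (i < 1) i = 1;
  double seg = arc[i] - arc[i-1];
  double f = seg > 0 ? (s - arc[i-1]) / seg : 0;
  x = net.px[e][i-1] + f * (net.px[e][i] - net.px[e][i-1]);
  y = net.py[e][i-1] + f * (net.py[e][i] - net.py[e][i-1]);
}

// direction of travel on link e: departing from end `end`, or arriving at the
// opposite node having entered at `end`
static void dep_vec(const Net& net, int e, int end, double& dx, double& dy) {
  int m = net.px[e].size();
  if (end == 0) { dx = net.px[e][1]   - net.px[e][0];   dy = net.py[e][1]   - net.py[e][0]; }
  else          { dx = net.px[e][m-2] - net.px[e][m-1]; dy = net.py[e][m-2] - net.py[e][m-1]; }
}
static void arr_vec(const Net& net, int e, int entry_end, double& dx, double& dy) {
  int m = net.px[e].size();
  if (entry_end == 0) { dx = net.px[e][m-1] - net.px[e][m-2]; dy = net.py[e][m-1] - net.py[e][m-2]; }
  else                { dx = net.px[e][0]   - net.px[e][1];   dy = net.py[e][0]   - net.py[e][1]; }
}

// ---------------------------------------------------------------------------
// Euclidean node distances from the origin point (arc s0 on link o), capped
// expansion at radius r. Exact for every node with true distance <= r.
static std::vector<double> node_distances(const Net& net, int o, double s0, double r) {
  std::vector<double> dist(net.nN, INF);
  typedef std::pair<double,int> QI;
  std::priority_queue<QI, std::vector<QI>, std::greater<QI> > pq;
  double da = s0, db = net.len[o] - s0;
  if (da < dist[net.na[o]]) { dist[net.na[o]] = da; pq.push(std::make_pair(da, net.na[o])); }
  if (db < dist[net.nb[o]]) { dist[net.nb[o]] = db; pq.push(std::make_pair(db, net.nb[o])); }
  while (!pq.empty()) {
    QI top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u] + 1e-12) continue;
    if (d > r) continue; // nodes beyond r need no expansion
    for (size_t k = 0; k < net.inc[u].size(); ++k) {
      int e = net.inc[u][k].first;
      int v = (net.inc[u][k].second == 0) ? net.nb[e] : net.na[e];
      double nd = d + net.len[e];
      if (nd < dist[v] - 1e-12) { dist[v] = nd; pq.push(std::make_pair(nd, v)); }
    }
  }
  return dist;
}

struct Interval { int e; double a, b; };

// merged included intervals for link e at radius r
static void link_intervals(const Net& net, const std::vector<double>& dist,
                           int o, double s0, int e, double r,
                           std::vector<std::pair<double,double> >& out) {
  out.clear();
  double L = net.len[e];
  std::vector<std::pair<double,double> > cand;
  double da = dist[net.na[e]], db = dist[net.nb[e]];
  if (da <= r) cand.push_back(std::make_pair(0.0, std::min(L, r - da)));
  if (db <= r) cand.push_back(std::make_pair(std::max(0.0, L - (r - db)), L));
  if (e == o) cand.push_back(std::make_pair(std::max(0.0, s0 - r), std::min(L, s0 + r)));
  if (cand.empty()) return;
  std::sort(cand.begin(), cand.end());
  double a = cand[0].first, b = cand[0].second;
  for (size_t i = 1; i < cand.size(); ++i) {
    if (cand[i].first <= b + TOL_ARC) b = std::max(b, cand[i].second);
    else { out.push_back(std::make_pair(a, b)); a = cand[i].first; b = cand[i].second; }
  }
  out.push_back(std::make_pair(a, b));
}

struct Member {
  int e;
  bool full;                 // whole link included
  double P;                  // included fraction x weight
  double included_len;
  std::vector<std::pair<double,double> > ivals; // arc intervals
};

struct Subsystem {
  int o; double s0, r; bool continuous;
  double ox, oy;             // origin point
  std::vector<Member> members;      // origin first
  std::vector<double> ndist;        // node distances
  std::vector<std::pair<double,double> > reached; // hull points
};

static void build_subsystem(const Net& net, int o, double s0, double r,
                            bool continuous, Subsystem& S,
                            const std::vector<double>* pre_dist = 0) {
  S.o = o; S.s0 = s0; S.r = r; S.continuous = continuous;
  point_at(net, o, s0, S.ox, S.oy);
  if (pre_dist) S.ndist = *pre_dist; else S.ndist = node_distances(net, o, s0, r);
  S.members.clear(); S.reached.clear();
  std::vector<std::pair<double,double> > iv;
  for (int e = 0; e < net.nL; ++e) {
    link_intervals(net, S.ndist, o, s0, e, r, iv);
    double L = net.len[e];
    bool full = (iv.size() == 1 && iv[0].first <= TOL_ARC && iv[0].second >= L - TOL_ARC);
    double inc_len = 0;
    for (size_t i = 0; i < iv.size(); ++i) inc_len += iv[i].second - iv[i].first;
    bool member;
    if (continuous) member = (inc_len > TOL_ARC) || e == o;
    else            member = full || e == o;
    if (!member) continue;
    Member M;
    M.e = e; M.full = full;
    if (continuous) {
      M.ivals = iv;
      if (iv.empty()) M.ivals.push_back(std::make_pair(s0, s0)); // r = 0 origin
      M.included_len = inc_len;
      M.P = (L > 0 ? inc_len / L : 0) * net.w[e];
    } else {
      M.ivals.clear();
      M.ivals.push_back(std::make_pair(0.0, L));
      M.included_len = L;
      M.P = net.w[e];
    }
    if (e == o) S.members.insert(S.members.begin(), M);
    else S.members.push_back(M);
  }
  // reached points: origin point + vertices of included portions + cut points
  S.reached.push_back(std::make_pair(S.ox, S.oy));
  for (size_t m = 0; m < S.members.size(); ++m) {
    const Member& M = S.members[m];
    int e = M.e;
    const std::vector<double>& arc = net.arc[e];
    if (!continuous) {
      for (size_t i = 0; i < arc.size(); ++i)
        S.reached.push_back(std::make_pair(net.px[e][i], net.py[e][i]));
    } else {
      for (size_t k = 0; k < M.ivals.size(); ++k) {
        double a = M.ivals[k].first, b = M.ivals[k].second;
        double x, y;
        point_at(net, e, a, x, y); S.reached.push_back(std::make_pair(x, y));
        point_at(net, e, b, x, y); S.reached.push_back(std::make_pair(x, y));
        for (size_t i = 0; i < arc.size(); ++i)
          if (arc[i] > a + TOL_ARC && arc[i] < b - TOL_ARC)
            S.reached.push_back(std::make_pair(net.px[e][i], net.py[e][i]));
      }
    }
  }
}

// ---------------------------------------------------------------------------
// convex hull statistics (monotone chain)
static double cross3(const std::pair<double,double>& o, const std::pair<double,double>& a,
                     const std::pair<double,double>& b) {
  return (a.first - o.first) * (b.second - o.second) -
         (a.second - o.second) * (b.first - o.first);
}

struct HullStats { double A, P, R, SI; bool si_defined; };

static HullStats hull_stats_points(std::vector<std::pair<double,double> > pts,
                                   double ox, double oy) {
  HullStats H; H.A = 0; H.P = 0; H.R = 0; H.SI = NA_REAL; H.si_defined = false;
  for (size_t i = 0; i < pts.size(); ++i)
    H.R = std::max(H.R, std::hypot(pts[i].first - ox, pts[i].second - oy));
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  size_t n = pts.size();
  if (n == 1) return H;
  std::vector<std::pair<double,double> > h(2 * n);
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {
    while (k >= 2 && cross3(h[k-2], h[k-1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  size_t lower = k + 1;
  for (size_t i = n - 1; i-- > 0; ) {
    while (k >= lower && cross3(h[k-2], h[k-1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1); // closed ring implied; last point == first removed
  double area = 0, per = 0, diam = 0;
  size_t hn = h.size();
  for (size_t i = 0; i < hn; ++i) {
    size_t j = (i + 1) % hn;
    area += h[i].first * h[j].second - h[j].first * h[i].second;
    per += std::hypot(h[j].first - h[i].first, h[j].second - h[i].second);
    for (size_t l = i + 1; l < hn; ++l)
      diam = std::max(diam, std::hypot(h[l].first - h[i].first, h[l].second - h[i].second));
  }
  area = std::fabs(area) / 2;
  // degenerate (collinear) hulls: zero area, perimeter = twice the extent
  if (hn < 3 || area < 1e-6 * std::max(1.0, diam * diam)) {
    H.A = 0; H.P = 2 * diam; H.SI = NA_REAL; H.si_defined = false;
    return H;
  }
  H.A = area; H.P = per;
  H.SI = per / (2 * std::sqrt(M_PI * area));
  H.si_defined = true;
  return H;
}

// ---------------------------------------------------------------------------
// angular geodesics within a subsystem

struct Label {
  double th, len; int hops; int pred; bool set;
  Label() : th(INF), len(INF), hops(0), pred(-9), set(false) {}
};

struct AngularResult {
  // one entry per destination interval (members after origin, per interval)
  std::vector<int> dest_e;
  std::vector<double> dest_rep, dest_P, th, len, crow;
  std::vector<bool> reachable;
  std::vector<std::vector<int> > paths; // link-id sequences incl. origin & dest
  int n_states;
};

// reconstruct the link sequence of the path ending at state st
static void state_path(const std::vector<Label>& lab, const std::vector<int>& st_link,
                       int o, int st, std::vector<int>& out) {
  out.clear();
  int cur = st;
  while (cur >= 0) { out.push_back(st_link[cur]); cur = lab[cur].pred; }
  out.push_back(o);
  std::reverse(out.begin(), out.end());
}

static int lex_compare_paths(const std::vector<int>& a, const std::vector<int>& b) {
  size_t n = std::min(a.size(), b.size());
  for (size_t i = 0; i < n; ++i) {
    if (a[i] < b[i]) return -1;
    if (a[i] > b[i]) return 1;
  }
  if (a.size() < b.size()) return -1;
  if (a.size() > b.size()) return 1;
  return 0;
}

// composite order: (theta ~TOL_TH, len ~TOL_LEN, hops, lex path)
static bool better_label(double th1, double l1, int h1,
                         const std::vector<Label>& lab, const std::vector<int>& st_link,
                         int o, int pred1, int via_link, int st_existing) {
  const Label& ex = lab[st_existing];
  if (!ex.set) return true;
  if (th1 < ex.th - TOL_TH) return true;
  if (th1 > ex.th + TOL_TH) return false;
  if (l1 < ex.len - TOL_LEN) return true;
  if (l1 > ex.len + TOL_LEN) return false;
  if (h1 < ex.hops) return true;
  if (h1 > ex.hops) return false;
  // exact tie: lexicographic on full link sequences
  std::vector<int> pnew, pold;
  if (pred1 >= 0) state_path(lab, st_link, o, pred1, pnew); else pnew.push_back(o);
  pnew.push_back(via_link);
  state_path(lab, st_link, o, st_existing, pold);
  return lex_compare_paths(pnew, pold) < 0;
}

static void angular_run(const Net& net, const Subsystem& S,
                        AngularResult& R, bool dest_angular_center) {
  int nm = S.members.size();
  // states: 2 per member link (entry at end 0 / end 1)
  std::vector<int> member_of(net.nL, -1);
  for (int m = 0; m < nm; ++m) member_of[S.members[m].e] = m;
  std::vector<int> st_link(2 * nm);
  std::vector<bool> st_valid(2 * nm, false);
  for (int m = 0; m < nm; ++m) {
    const Member& M = S.members[m];
    st_link[2*m] = M.e; st_link[2*m+1] = M.e;
    double L = net.len[M.e];
    for (size_t k = 0; k < M.ivals.size(); ++k) {
      if (M.ivals[k].first <= TOL_ARC) st_valid[2*m] = true;       // enterable at a
      if (M.ivals[k].second >= L - TOL_ARC) st_valid[2*m+1] = true; // enterable at b
    }
  }
  std::vector<Label> lab(2 * nm);
  typedef std::pair<std::pair<double,double>, int> QI; // ((theta,len), state)
  std::priority_queue<QI, std::vector<QI>, std::greater<QI> > pq;

  int o = S.o; double s0 = S.s0;
  // pseudo-source: leave the origin link via either end
  for (int side = 0; side < 2; ++side) {
    int node = (side == 0) ? net.na[o] : net.nb[o];
    double th0 = (side == 0) ? internal_cost(net, o, 0, s0)
                             : internal_cost(net, o, s0, net.len[o]);
    double l0 = (side == 0) ? s0 : net.len[o] - s0;
    // in continuous space the walk to this end must itself stay in radius
    if (S.continuous && l0 > S.r + TOL_ARC) continue;
    double ax, ay; // arrival direction at the node
    if (side == 0) arr_vec(net, o, 1, ax, ay); else arr_vec(net, o, 0, ax, ay);
    for (size_t k = 0; k < net.inc[node].size(); ++k) {
      int f = net.inc[node][k].first, u = net.inc[node][k].second;
      if (f == o) continue; // no immediate U-turn back onto the origin link
      int mf = member_of[f];
      if (mf < 0) continue;
      int st = 2 * mf + u;
      if (!st_valid[st]) continue;
      double dx, dy; dep_vec(net, f, u, dx, dy);
      double th = th0 + angle_deg(ax, ay, dx, dy);
      int predmark = (side == 0) ? -1 : -2;
      if (better_label(th, l0, 2, lab, st_link, o, predmark, f, st)) {
        lab[st].th = th; lab[st].len = l0; lab[st].hops = 2;
        lab[st].pred = predmark; lab[st].set = true;
        pq.push(std::make_pair(std::make_pair(th, l0), st));
      }
    }
  }
  while (!pq.empty()) {
    QI top = pq.top(); pq.pop();
    int st = top.second;
    if (top.first.first > lab[st].th + TOL_TH ||
        (std::fabs(top.first.first - lab[st].th) <= TOL_TH &&
         top.first.second > lab[st].len + TOL_LEN)) continue;
    int e = st_link[st], entry = st & 1;
    int me = member_of[e];
    if (!S.members[me].full) continue; // partial links are destinations only
    int exit_node = (entry == 0) ? net.nb[e] : net.na[e];
    double th_exit = lab[st].th + internal_cost(net, e, 0, net.len[e]);
    double len_exit = lab[st].len + net.len[e];
    double ax, ay; arr_vec(net, e, entry, ax, ay);
    for (size_t k = 0; k < net.inc[exit_node].size(); ++k) {
      int f = net.inc[exit_node][k].first, u = net.inc[exit_node][k].second;
      if (f == e) continue; // no immediate U-turn
      int mf = member_of[f];
      if (mf < 0) continue;
      int st2 = 2 * mf + u;
      if (!st_valid[st2]) continue;
      double dx, dy; dep_vec(net, f, u, dx, dy);
      double th2 = th_exit + angle_deg(ax, ay, dx, dy);
      if (better_label(th2, len_exit, lab[st].hops + 1, lab, st_link, o, st, f, st2)) {
        lab[st2].th = th2; lab[st2].len = len_exit;
        lab[st2].hops = lab[st].hops + 1; lab[st2].pred = st; lab[st2].set = true;
        pq.push(std::make_pair(std::make_pair(th2, len_exit), st2));
      }
    }
  }
  // destination costs per member interval (origin excluded)
  R.dest_e.clear(); R.dest_rep.clear(); R.dest_P.clear();
  R.th.clear(); R.len.clear(); R.crow.clear(); R.reachable.clear(); R.paths.clear();
  R.n_states = 2 * nm;
  for (int m = 0; m < nm; ++m) {
    const Member& M = S.members[m];
    if (M.e == o) continue;
    double L = net.len[M.e];
    for (size_t k = 0; k < M.ivals.size(); ++k) {
      double a = M.ivals[k].first, b = M.ivals[k].second;
      double rep;
      if (!S.continuous && dest_angular_center) {
        // angular center: first arc where cumulative deflection reaches half
        double half = internal_cost(net, M.e, 0, L) / 2;
        if (half <= 0) rep = L / 2;
        else {
          rep = L / 2; double cum = 0;
          const std::vector<double>& arc = net.arc[M.e];
          for (size_t i = 1; i + 1 < arc.size(); ++i) {
            cum += angle_deg(net.px[M.e][i] - net.px[M.e][i-1], net.py[M.e][i] - net.py[M.e][i-1],
                             net.px[M.e][i+1] - net.px[M.e][i], net.py[M.e][i+1] - net.py[M.e][i]);
            if (cum >= half - 1e-12) { rep = arc[i]; break; }
          }
        }
      } else {
        rep = (a + b) / 2;
      }
      double Pk = S.continuous ? ((b - a) / std::max(L, 1e-300)) * net.w[M.e] : net.w[M.e];
      double rx, ry; point_at(net, M.e, rep, rx, ry);
      double crow = std::hypot(rx - S.ox, ry - S.oy);
      // best entry among the ends this interval touches
      double bth = INF, blen = INF; int bst = -1;
      for (int entry = 0; entry < 2; ++entry) {
        int st = 2 * m + entry;
        if (!st_valid[st] || !lab[st].set) continue;
        bool touches = (entry == 0) ? (a <= TOL_ARC) : (b >= L - TOL_ARC);
        if (!touches) continue;
        double th = lab[st].th + (entry == 0 ? internal_cost(net, M.e, 0, rep)
                                             : internal_cost(net, M.e, rep, L));
        double ln = lab[st].len + (entry == 0 ? rep : L - rep);
        bool take = false;
        if (bst < 0) take = true;
        else if (th < bth - TOL_TH) take = true;
        else if (th <= bth + TOL_TH && ln < blen - TOL_LEN) take = true;
        else if (th <= bth + TOL_TH && ln <= blen + TOL_LEN) {
          std::vector<int> p1, p2;
          state_path(lab, st_link, o, st, p1);
          state_path(lab, st_link, o, bst, p2);
          if (lex_compare_paths(p1, p2) < 0) take = true;
        }
        if (take) { bth = th; blen = ln; bst = st; }
      }
      R.dest_e.push_back(M.e);
      R.dest_rep.push_back(rep);
      R.dest_P.push_back(Pk);
      R.crow.push_back(crow);
      if (bst >= 0) {
        R.th.push_back(bth); R.len.push_back(blen); R.reachable.push_back(true);
        std::vector<int> p; state_path(lab, st_link, o, bst, p);
        R.paths.push_back(p);
      } else {
        R.th.push_back(NA_REAL); R.len.push_back(NA_REAL); R.reachable.push_back(false);
        R.paths.push_back(std::vector<int>());
      }
    }
  }
}

// ---------------------------------------------------------------------------
// full per-origin metric row + betweenness contributions

struct BtAcc { std::vector<double> BtA, TPBtA, TPDA; };

static void origin_metrics(const Net& net, const Subsystem& S, double delta_deg,
                           double* out13, int& dropped, BtAcc* bt,
                           bool dest_angular = false) {
  double links = 0, length = 0;
  for (size_t m = 0; m < S.members.size(); ++m) {
    links += S.members[m].P;
    length += S.members[m].included_len;
  }
  AngularResult R;
  angular_run(net, S, R, dest_angular);
  double nq = 0, sP = 0, sMG = 0, sMC = 0, sMA = 0, sDiv = 0, sPdiv = 0;
  dropped = 0;
  for (size_t i = 0; i < R.dest_e.size(); ++i) {
    if (!R.reachable[i]) { ++dropped; continue; }
    double P = R.dest_P[i];
    nq += P / std::max(R.th[i], delta_deg);
    sP += P;
    sMG += P * R.len[i];
    sMC += P * R.crow[i];
    sMA += P * R.th[i];
    if (R.crow[i] > 1e-9) { sDiv += P * (R.len[i] / R.crow[i]); sPdiv += P; }
  }
  double mgla = sP > 0 ? sMG / sP : NA_REAL;
  double mcf  = sP > 0 ? sMC / sP : NA_REAL;
  double mad  = sP > 0 ? sMA / sP : NA_REAL;
  double diva = sPdiv > 0 ? sDiv / sPdiv : NA_REAL;
  int jnc = 0, con = 0;
  for (int n = 0; n < net.nN; ++n) {
    if (net.degree[n] >= 3 && S.ndist[n] <= S.r + TOL_ARC) {
      ++jnc; con += net.degree[n];
    }
  }
  HullStats H = hull_stats_points(S.reached, S.ox, S.oy);
  out13[0] = links; out13[1] = length; out13[2] = nq;
  out13[3] = mgla; out13[4] = mcf; out13[5] = mad; out13[6] = diva;
  out13[7] = jnc; out13[8] = con;
  out13[9] = H.A; out13[10] = H.P; out13[11] = H.R;
  out13[12] = H.si_defined ? H.SI : NA_REAL;

  if (bt) {
    double W = net.w[S.o];
    double totP = 0;
    for (size_t m = 0; m < S.members.size(); ++m) totP += S.members[m].P;
    double Po = S.members.empty() ? 0 : S.members[0].P; // origin is first
    if (totP > 0) {
      // self pair y = z: sigma = 1/3
      bt->BtA[S.o] += W * Po / 3.0;
      bt->TPBtA[S.o] += W * (Po / totP) / 3.0;
      bt->TPDA[S.o] += W * Po / totP;
      for (size_t i = 0; i < R.dest_e.size(); ++i) {
        double P = R.dest_P[i];
        bt->TPDA[R.dest_e[i]] += W * P / totP; // gated on radius membership
        if (!R.reachable[i]) continue;
        const std::vector<int>& path = R.paths[i];
        for (size_t j = 0; j < path.size(); ++j) {
          double sigma = (j == 0 || j == path.size() - 1) ? 0.5 : 1.0;
          bt->BtA[path[j]] += W * P * sigma;
          bt->TPBtA[path[j]] += W * (P / totP) * sigma;
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export]]
List cpp_metrics_all(List netlist, NumericVector s0, NumericVector radii,
                     bool continuous, double delta_deg, bool betweenness) {
  Net net = make_net(netlist);
  int nR = radii.size();
  NumericVector metrics(Dimension(net.nL, 13, nR));
  IntegerMatrix dropped(net.nL, nR);
  List btout(nR);
  for (int ri = 0; ri < nR; ++ri) {
    double r = radii[ri];
    BtAcc bt;
    bt.BtA.assign(net.nL, 0); bt.TPBtA.assign(net.nL, 0); bt.TPDA.assign(net.nL, 0);
    for (int o = 0; o < net.nL; ++o) {
      Subsystem S;
      build_subsystem(net, o, s0[o], r, continuous, S);
      double row[13]; int drop = 0;
      origin_metrics(net, S, delta_deg, row, drop, betweenness ? &bt : 0);
      for (int j = 0; j < 13; ++j) metrics[o + net.nL * (j + 13 * ri)] = row[j];
      dropped(o, ri) = drop;
      if (o % 256 == 0) Rcpp::checkUserInterrupt();
    }
    btout[ri] = List::create(_["BtA"] = wrap(bt.BtA), _["TPBtA"] = wrap(bt.TPBtA),
                             _["TPDA"] = wrap(bt.TPDA));
  }
  return List::create(_["metrics"] = metrics, _["dropped"] = dropped,
                      _["betweenness"] = btout);
}

// HullR only, all links x all radii (shared Dijkstra per origin at max radius)
// [[Rcpp::export]]
NumericMatrix cpp_hullr_profile(List netlist, NumericVector s0, NumericVector radii,
                                bool continuous) {
  Net net = make_net(netlist);
  int nR = radii.size();
  double rmax = 0;
  for (int i = 0; i < nR; ++i) rmax = std::max(rmax, radii[i]);
  NumericMatrix out(net.nL, nR);
  for (int o = 0; o < net.nL; ++o) {
    std::vector<double> dist = node_distances(net, o, s0[o], rmax);
    for (int ri = 0; ri < nR; ++ri) {
      Subsystem S;
      // node distances valid for any r <= rmax
      build_subsystem(net, o, s0[o], radii[ri], continuous, S, &dist);
      double R = 0;
      for (size_t i = 0; i < S.reached.size(); ++i)
        R = std::max(R, std::hypot(S.reached[i].first - S.ox, S.reached[i].second - S.oy));
      out(o, ri) = R;
    }
    if (o % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_subsystem(List netlist, int origin, double s0, double r, bool continuous) {
  Net net = make_net(netlist);
  Subsystem S;
  build_subsystem(net, origin - 1, s0, r, continuous, S);
  int nm = S.members.size();
  std::vector<int> e; std::vector<double> a, b, P; std::vector<bool> full;
  for (int m = 0; m < nm; ++m) {
    for (size_t k = 0; k < S.members[m].ivals.size(); ++k) {
      e.push_back(S.members[m].e + 1);
      a.push_back(S.members[m].ivals[k].first);
      b.push_back(S.members[m].ivals[k].second);
      double L = net.len[S.members[m].e];
      P.push_back(continuous
        ? ((S.members[m].ivals[k].second - S.members[m].ivals[k].first) / std::max(L, 1e-300)) * net.w[S.members[m].e]
        : net.w[S.members[m].e]);
      full.push_back(S.members[m].full);
    }
  }
  NumericMatrix pts(S.reached.size(), 2);
  for (size_t i = 0; i < S.reached.size(); ++i) {
    pts(i, 0) = S.reached[i].first; pts(i, 1) = S.reached[i].second;
  }
  HullStats H = hull_stats_points(S.reached, S.ox, S.oy);
  return List::create(
    _["link"] = wrap(e), _["arc_from"] = wrap(a), _["arc_to"] = wrap(b),
    _["P"] = wrap(P), _["full"] = wrap(full),
    _["origin_x"] = S.ox, _["origin_y"] = S.oy,
    _["node_dist"] = wrap(S.ndist), _["reached_points"] = pts,
    _["hull"] = NumericVector::create(_["HullA"] = H.A, _["HullP"] = H.P,
                                      _["HullR"] = H.R,
                                      _["HullSI"] = H.si_defined ? H.SI : NA_REAL));
}

// [[Rcpp::export]]
List cpp_geodesics(List netlist, int origin, double s0, double r, bool continuous) {
  Net net = make_net(netlist);
  Subsystem S;
  build_subsystem(net, origin - 1, s0, r, continuous, S);
  AngularResult R;
  angular_run(net, S, R, false);
  int n = R.dest_e.size();
  IntegerVector de(n); NumericVector rep(n), P(n), th(n), len(n), crow(n);
  LogicalVector reach(n);
  List paths(n);
  for (int i = 0; i < n; ++i) {
    de[i] = R.dest_e[i] + 1;
    rep[i] = R.dest_rep[i]; P[i] = R.dest_P[i];
    th[i] = R.th[i]; len[i] = R.len[i]; crow[i] = R.crow[i];
    reach[i] = (bool)R.reachable[i];
    IntegerVector p(R.paths[i].size());
    for (size_t j = 0; j < R.paths[i].size(); ++j) p[j] = R.paths[i][j] + 1;
    paths[i] = p;
  }
  return List::create(_["link"] = de, _["rep_arc"] = rep, _["P"] = P,
                      _["angular_cost_deg"] = th, _["network_length_m"] = len,
                      _["crow_flight_m"] = crow, _["reachable"] = reach,
                      _["path"] = paths);
}
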