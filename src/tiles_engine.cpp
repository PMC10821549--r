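// Streaming overlapping-community engine over an edge birth/death stream.
//
// Communities carry two membership levels. Core members each sit in at
// least one triangle whose three vertices are all core members of the same
// community; peripheral members are the one-hop neighbours of the core.
// Only core members propagate community labels. Births create communities
// from fresh triangles and cascade core promotions; deaths demote cores
// that lost their last all-core triangle, split communities whose core
// subgraph disconnects, and dissolve communities with fewer than three
// cores. All containers are ordered so replaying an identical stream
// reproduces identical community ids and member sets.

#include <Rcpp.h>
#include <map>
#include <queue>
#include <set>
#include <vector>

using namespace Rcpp;

struct Community {
  std::set<int> core;
  std::set<int> peri;
};

class Engine {
public:
  explicit Engine(int n_nodes)
      : n(n_nodes), adj(n_nodes + 1), core_of(n_nodes + 1) {}

  int n;
  std::vector<std::set<int> > adj;      // 1-based node ids
  std::map<int, Community> comms;       // live communities by cid
  std::vector<std::set<int> > core_of;  // node -> cids where node is core
  int next_cid = 1;
  int n_obs = 0;

  // observation history, column-wise
  std::vector<int> h_window, h_cid, h_node, h_role;  // role: 1 core, 0 peri

  void check_node(int x) const {
    if (x < 1 || x > n) stop("node id out of range");
  }

  std::vector<int> common_neighbors(int u, int v) const {
    std::vector<int> z;
    const std::set<int>& a = adj[u].size() <= adj[v].size() ? adj[u] : adj[v];
    const std::set<int>& b = adj[u].size() <= adj[v].size() ? adj[v] : adj[u];
    for (std::set<int>::const_iterator it = a.begin(); it != a.end(); ++it)
      if (b.count(*it)) z.push_back(*it);
    return z;  // sorted: std::set iteration order
  }

  void promote(int cid, int w, std::queue<std::pair<int, int> >& q,
               std::set<int>& affected) {
    std::map<int, Community>::iterator it = comms.find(cid);
    if (it == comms.end()) return;
    Community& c = it->second;
    if (c.core.count(w)) return;
    c.core.insert(w);
    c.peri.erase(w);
    core_of[w].insert(cid);
    affected.insert(cid);
    q.push(std::make_pair(w, cid));
  }

  // A newly promoted core w may complete triangles (w, a, b) with a core a:
  // then b must become core too ("only core members transmit membership").
  void cascade(std::queue<std::pair<int, int> >& q, std::set<int>& affected) {
    while (!q.empty()) {
      int w = q.front().first, cid = q.front().second;
      q.pop();
      std::map<int, Community>::iterator it = comms.find(cid);
      if (it == comms.end()) continue;
      Community& c = it->second;
      if (!c.core.count(w)) continue;
      std::vector<int> nb(adj[w].begin(), adj[w].end());
      for (size_t i = 0; i < nb.size(); ++i) {
        int a = nb[i];
        if (!c.core.count(a)) continue;
        const std::set<int>& sm = adj[w].size() <= adj[a].size() ? adj[w] : adj[a];
        const std::set<int>& bg = adj[w].size() <= adj[a].size() ? adj[a] : adj[w];
        for (std::set<int>::const_iterator bt = sm.begin(); bt != sm.end(); ++bt) {
          int b = *bt;
          if (b == w || b == a) continue;
          if (bg.count(b) && !c.core.count(b)) promote(cid, b, q, affected);
        }
      }
    }
  }

  void birth(int u, int v) {
    check_node(u);
    check_node(v);
    if (u == v) stop("self-loop birth");
    if (adj[u].count(v)) stop("birth of an already present edge");
    adj[u].insert(v);
    adj[v].insert(u);

    std::vector<int> Z = common_neighbors(u, v);
    std::set<int> affected;
    std::queue<std::pair<int, int> > q;
    for (size_t zi = 0; zi < Z.size(); ++zi) {
      int z = Z[zi];
      int tri[3] = {u, v, z};
      std::map<int, int> cnt;
      for (int k = 0; k < 3; ++k) {
        const std::set<int>& cs = core_of[tri[k]];
        for (std::set<int>::const_iterator c = cs.begin(); c != cs.end(); ++c)
          cnt[*c]++;
      }
      bool matched = false;
      for (std::map<int, int>::iterator c = cnt.begin(); c != cnt.end(); ++c) {
        if (c->second >= 2) {
          matched = true;
          for (int k = 0; k < 3; ++k)
            if (!comms[c->first].core.count(tri[k]))
              promote(c->first, tri[k], q, affected);
        }
      }
      if (!matched) {  // fresh triangle: found a new community
        int cid = next_cid++;
        Community c;
        for (int k = 0; k < 3; ++k) {
          c.core.insert(tri[k]);
          core_of[tri[k]].insert(cid);
        }
        comms[cid] = c;
        affected.insert(cid);
        for (int k = 0; k < 3; ++k) q.push(std::make_pair(tri[k], cid));
      }
    }
    cascade(q, affected);
    finish_event(u, v, affected);
  }

  bool has_all_core_triangle(const Community& c, int m) const {
    std::vector<int> cn;
    for (std::set<int>::const_iterator it = adj[m].begin(); it != adj[m].end();
         ++it)
      if (c.core.count(*it)) cn.push_back(*it);
    for (size_t i = 0; i < cn.size(); ++i)
      for (size_t j = i + 1; j < cn.size(); ++j)
        if (adj[cn[i]].count(cn[j])) return true;
    return false;
  }

  void death(int u, int v) {
    check_node(u);
    check_node(v);
    if (!adj[u].count(v)) stop("death of an absent edge");
    // communities that may lose triangles: those holding u or v as core
    std::set<int> cids(core_of[u].begin(), core_of[u].end());
    cids.insert(core_of[v].begin(), core_of[v].end());
    std::vector<int> zc = common_neighbors(u, v);
    adj[u].erase(v);
    adj[v].erase(u);

    std::set<int> affected;
    for (std::set<int>::iterator ci = cids.begin(); ci != cids.end(); ++ci) {
      int cid = *ci;
      std::map<int, Community>::iterator it = comms.find(cid);
      if (it == comms.end()) continue;
      Community& c = it->second;
      bool both_core = c.core.count(u) && c.core.count(v);

      // localized demotion fixpoint: only u, v and their common neighbours
      // lost a triangle directly; demotions propagate to core neighbours
      std::queue<int> dq;
      if (c.core.count(u)) dq.push(u);
      if (c.core.count(v)) dq.push(v);
      for (size_t k = 0; k < zc.size(); ++k)
        if (c.core.count(zc[k])) dq.push(zc[k]);
      bool changed = false;
      while (!dq.empty()) {
        int m = dq.front();
        dq.pop();
        if (!c.core.count(m)) continue;
        if (has_all_core_triangle(c, m)) continue;
        c.core.erase(m);
        core_of[m].erase(cid);
        changed = true;
        for (std::set<int>::const_iterator nb = adj[m].begin();
             nb != adj[m].end(); ++nb)
          if (c.core.count(*nb)) dq.push(*nb);
      }
      affected.insert(cid);
      if (c.core.size() < 3) {  // dissolve
        for (std::set<int>::iterator m = c.core.begin(); m != c.core.end(); ++m)
          core_of[*m].erase(cid);
        comms.erase(cid);
        continue;
      }
      if (changed || both_core) split_if_disconnected(cid, affected);
    }
    finish_event(u, v, affected);
  }

  void split_if_disconnected(int cid, std::set<int>& affected) {
    Community& c = comms[cid];
    std::vector<std::vector<int> > comps;
    std::set<int> seen;
    for (std::set<int>::iterator s = c.core.begin(); s != c.core.end(); ++s) {
      if (seen.count(*s)) continue;
      std::vector<int> comp, stack(1, *s);
      seen.insert(*s);
      while (!stack.empty()) {
        int m = stack.back();
        stack.pop_back();
        comp.push_back(m);
        for (std::set<int>::const_iterator nb = adj[m].begin();
             nb != adj[m].end(); ++nb)
          if (c.core.count(*nb) && !seen.count(*nb)) {
            seen.insert(*nb);
            stack.push_back(*nb);
          }
      }
      comps.push_back(comp);
    }
    if (comps.size() <= 1) return;
    // component holding the smallest core node keeps the cid; the rest get
    // fresh cids in order of their smallest member (deterministic)
    c.core.clear();
    c.core.insert(comps[0].begin(), comps[0].end());
    for (size_t k = 1; k < comps.size(); ++k) {
      for (size_t m = 0; m < comps[k].size(); ++m)
        core_of[comps[k][m]].erase(cid);
      if (comps[k].size() >= 3) {
        int ncid = next_cid++;
        Community nc;
        nc.core.insert(comps[k].begin(), comps[k].end());
        for (size_t m = 0; m < comps[k].size(); ++m)
          core_of[comps[k][m]].insert(ncid);
        comms[ncid] = nc;
        affected.insert(ncid);
      }
    }
    affected.insert(cid);
  }

  // refresh peripheral sets of affected communities, then collapse live
  // communities whose core sets became identical (smaller cid survives)
  void finish_event(int u, int v, std::set<int>& affected) {
    int uv[2] = {u, v};
    for (int k = 0; k < 2; ++k) {
      const std::set<int>& cs = core_of[uv[k]];
      affected.insert(cs.begin(), cs.end());
      for (std::set<int>::const_iterator nb = adj[uv[k]].begin();
           nb != adj[uv[k]].end(); ++nb)
        affected.insert(core_of[*nb].begin(), core_of[*nb].end());
    }
    for (std::set<int>::iterator ci = affected.begin(); ci != affected.end();
         ++ci) {
      std::map<int, Community>::iterator it = comms.find(*ci);
      if (it == comms.end()) continue;
      Community& c = it->second;
      c.peri.clear();
      for (std::set<int>::iterator m = c.core.begin(); m != c.core.end(); ++m)
        for (std::set<int>::const_iterator nb = adj[*m].begin();
             nb != adj[*m].end(); ++nb)
          if (!c.core.count(*nb)) c.peri.insert(*nb);
    }
    // duplicate-core collapse
    std::vector<int> drop;
    for (std::set<int>::iterator ci = affected.begin(); ci != affected.end();
         ++ci) {
      std::map<int, Community>::iterator it = comms.find(*ci);
      if (it == comms.end()) continue;
      for (std::map<int, Community>::iterator jt = comms.begin();
           jt != comms.end(); ++jt) {
        if (jt->first >= it->first) break;
        if (jt->second.core == it->second.core) {
          drop.push_back(it->first);
          break;
        }
      }
    }
    for (size_t k = 0; k < drop.size(); ++k) {
      std::map<int, Community>::iterator it = comms.find(drop[k]);
      if (it == comms.end()) continue;
      for (std::set<int>::iterator m = it->second.core.begin();
           m != it->second.core.end(); ++m)
        core_of[*m].erase(drop[k]);
      comms.erase(it);
    }
  }

  void observe() {
    ++n_obs;
    for (std::map<int, Community>::iterator it = comms.begin();
         it != comms.end(); ++it) {
      for (std::set<int>::iterator m = it->second.core.begin();
           m != it->second.core.end(); ++m) {
        h_window.push_back(n_obs);
        h_cid.push_back(it->first);
        h_node.push_back(*m);
        h_role.push_back(1);
      }
      for (std::set<int>::iterator m = it->second.peri.begin();
           m != it->second.peri.end(); ++m) {
        h_window.push_back(n_obs);
        h_cid.push_back(it->first);
        h_node.push_back(*m);
        h_role.push_back(0);
      }
    }
  }
};

// [[Rcpp::export]]
SEXP tiles_engine_new(int n_nodes) {
  XPtr<Engine> p(new Engine(n_nodes), true);
  return p;
}

// [[Rcpp::export]]
void tiles_engine_birth(SEXP ptr, int u, int v) {
  XPtr<Engine>(ptr)->birth(u, v);
}

// [[Rcpp::export]]
void tiles_engine_death(SEXP ptr, int u, int v) {
  XPtr<Engine>(ptr)->death(u, v);
}

// [[Rcpp::export]]
void tiles_engine_observe(SEXP ptr) {
  XPtr<Engine>(ptr)->observe();
}

// Process a whole stream: events must be sorted by time with deaths before
// births inside one timestep; observations fire after every `window`-th
// timestep and once more after the final timestep if it is off-boundary.
// [[Rcpp::export]]
void tiles_engine_run(SEXP ptr, IntegerVector time, IntegerVector birth,
                      IntegerVector u, IntegerVector v, int window,
                      int total_t) {
  XPtr<Engine> e(ptr);
  if (window < 1) stop("observation window must be >= 1");
  R_xlen_t i = 0, m = time.size();
  for (int t = 1; t <= total_t; ++t) {
    while (i < m && time[i] == t) {
      if (birth[i]) e->birth(u[i], v[i]);
      else e->death(u[i], v[i]);
      ++i;
    }
    if (i < m && time[i] < t) stop("stream events are not sorted by time");
    if (t % window == 0) e->observe();
  }
  if (total_t >= 1 && total_t % window != 0) e->observe();
}

// [[Rcpp::export]]
List tiles_engine_live(SEXP ptr) {
  XPtr<Engine> e(ptr);
  List out(e->comms.size());
  int k = 0;
  for (std::map<int, Community>::iterator it = e->comms.begin();
       it != e->comms.end(); ++it, ++k) {
    out[k] = List::create(
        Named("cid") = it->first,
        Named("core") = IntegerVector(it->second.core.begin(),
                                      it->second.core.end()),
        Named("peripheral") = IntegerVector(it->second.peri.begin(),
                                            it->second.peri.end()));
  }
  return out;
}

// [[Rcpp::export]]
List tiles_engine_history(SEXP ptr) {
  XPtr<Engine> e(ptr);
  return List::create(Named("window") = wrap(e->h_window),
                      Named("cid") = wrap(e->h_cid),
                      Named("node") = wrap(e->h_node),
                      Named("core") = wrap(e->h_role));
}

// [[Rcpp::export]]
List tiles_engine_graph(SEXP ptr) {
  XPtr<Engine> e(ptr);
  std::vector<int> us, vs;
  for (int a = 1; a <= e->n; ++a)
    for (std::set<int>::iterator b = e->adj[a].begin(); b != e->adj[a].end();
         ++b)
      if (*b > a) {
        us.push_back(a);
        vs.push_back(*b);
      }
  return List::create(Named("u") = wrap(us), Named("v") = wrap(vs));
}
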