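// Lattice engine for contact-inhibited epithelial growth.
//
// The grid is an integer label matrix (0 = free, otherwise 1-based agent id)
// stored column-major like an R matrix: pixel p = y + x * H.  Footprints are
// 8-connected pixel sets grown by nearest-free-pixel accretion around an
// anchor, which yields quasi-circular blobs.  All randomness goes through R's
// RNG (unif_rand) so set.seed() fully determines trajectories.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const int OUT_DIVIDED = 0;     // daughter placed at max_area
const int OUT_COMPRESSED = 1;  // daughters compressed below max_area
const int OUT_BLOCKED = 2;     // no room for two footprints >= min_area
const int OUT_CONVERTED = 3;   // division limit reached -> senescent

struct QPix {
  int p;
  double d;
};
struct QPixCmp {
  bool operator()(const QPix& a, const QPix& b) const {
    if (a.d != b.d) return a.d > b.d;
    return a.p > b.p;  // deterministic tie-break
  }
};
typedef std::priority_queue<QPix, std::vector<QPix>, QPixCmp> PixQueue;

struct Engine {
  int W, H, WH;
  std::vector<int> grid;  // 0 or agent id (1-based)
  // per-agent state, index = id - 1
  std::vector<int> cls;      // 0 normal, 1 variant
  std::vector<int> st;       // 0 proliferative, 1 senescent
  std::vector<int> divs;     // divisions completed
  std::vector<int> limit;    // division limit, -1 = unbounded
  std::vector<double> phase; // hours into current cycle
  std::vector<int> area;
  std::vector<double> sx, sy;  // coordinate sums for centroids
  std::vector<std::vector<int> > pix;
  std::vector<int> stamp, stamp2;
  int cur, cur2;
  int occupied;

  double cycle, dtv;
  int min_area, max_area, radius;

  void init_grid(const IntegerMatrix& g) {
    H = g.nrow();
    W = g.ncol();
    WH = W * H;
    grid.assign(g.begin(), g.end());
    stamp.assign(WH, 0);
    stamp2.assign(WH, 0);
    cur = cur2 = 0;
    occupied = 0;
  }

  void init_agents(const IntegerVector& cls_, const IntegerVector& st_,
                   const IntegerVector& divs_, const IntegerVector& limit_,
                   const NumericVector& phase_) {
    int n = cls_.size();
    cls.assign(cls_.begin(), cls_.end());
    st.assign(st_.begin(), st_.end());
    divs.assign(divs_.begin(), divs_.end());
    limit.assign(limit_.begin(), limit_.end());
    phase.assign(phase_.begin(), phase_.end());
    area.assign(n, 0);
    sx.assign(n, 0.0);
    sy.assign(n, 0.0);
    pix.assign(n, std::vector<int>());
    for (int p = 0; p < WH; ++p) {
      int id = grid[p];
      if (id > 0) {
        if (id > n) stop("grid references agent id beyond agent table");
        int a = id - 1;
        pix[a].push_back(p);
        area[a]++;
        sx[a] += p / H;
        sy[a] += p % H;
        occupied++;
      }
    }
  }

  inline double cx(int a) const { return sx[a] / area[a]; }
  inline double cy(int a) const { return sy[a] / area[a]; }

  // Claim up to `target` free pixels forming an 8-connected blob seeded at
  // `seed`, preferring pixels closest to the anchor point.  Returns achieved.
  int accrete(int a, int seed, double ax, double ay, int target) {
    if (target <= 0 || grid[seed] != 0) return 0;
    int id = a + 1;
    ++cur;
    PixQueue q;
    stamp[seed] = cur;
    q.push(QPix{seed, 0.0});
    int got = 0;
    while (!q.empty() && got < target) {
      QPix t = q.top();
      q.pop();
      if (grid[t.p] != 0) continue;
      grid[t.p] = id;
      pix[a].push_back(t.p);
      int x = t.p / H, y = t.p % H;
      sx[a] += x;
      sy[a] += y;
      ++got;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dx && !dy) continue;
          int nx = x + dx, ny = y + dy;
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int np = ny + nx * H;
          if (grid[np] == 0 && stamp[np] != cur) {
            stamp[np] = cur;
            double ddx = nx - ax, ddy = ny - ay;
            q.push(QPix{np, ddx * ddx + ddy * ddy});
          }
        }
      }
    }
    area[a] += got;
    occupied += got;
    return got;
  }

  // Release the last `k` pixels claimed for agent a (used for rollback).
  void release_tail(int a, int k) {
    for (int i = 0; i < k; ++i) {
      int p = pix[a].back();
      pix[a].pop_back();
      grid[p] = 0;
      sx[a] -= p / H;
      sy[a] -= p % H;
    }
    area[a] -= k;
    occupied -= k;
  }

  // Free pixels reachable through free space within `rad` BFS layers
  // (8-connected) of the agent's footprint.  Optionally collects the first
  // layer (free pixels touching the footprint) into `frontier1`.
  int free_area(int a, int rad, std::vector<int>* frontier1 = NULL) {
    ++cur;
    std::vector<int> frontier;
    for (size_t i = 0; i < pix[a].size(); ++i) {
      int p = pix[a][i];
      int x = p / H, y = p % H;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dx && !dy) continue;
          int nx = x + dx, ny = y + dy;
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int np = ny + nx * H;
          if (grid[np] == 0 && stamp[np] != cur) {
            stamp[np] = cur;
            frontier.push_back(np);
          }
        }
      }
    }
    if (frontier1) *frontier1 = frontier;
    int count = (int)frontier.size();
    for (int depth = 1; depth < rad && !frontier.empty(); ++depth) {
      std::vector<int> nxt;
      for (size_t i = 0; i < frontier.size(); ++i) {
        int p = frontier[i];
        int x = p / H, y = p % H;
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dy = -1; dy <= 1; ++dy) {
            if (!dx && !dy) continue;
            int nx = x + dx, ny = y + dy;
            if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
            int np = ny + nx * H;
            if (grid[np] == 0 && stamp[np] != cur) {
              stamp[np] = cur;
              nxt.push_back(np);
            }
          }
        }
      }
      count += (int)nxt.size();
      frontier.swap(nxt);
    }
    return count;
  }

  // Shrink agent a to `keep` pixels, retaining a connected blob anchored at
  // `anchor_px` (an owned pixel), or around the centroid when anchor_px < 0;
  // freed pixels become empty.  Returns the freed pixels.
  std::vector<int> shrink(int a, int keep, int anchor_px = -1) {
    std::vector<int> freed;
    if (keep >= area[a]) return freed;
    int id = a + 1;
    double ax, ay;
    int start;
    double best = 1e30;
    if (anchor_px >= 0) {
      start = anchor_px;
      ax = anchor_px / H;
      ay = anchor_px % H;
      best = 0.0;
    } else {
      ax = cx(a);
      ay = cy(a);
      // start from the owned pixel closest to the centroid
      start = pix[a][0];
      for (size_t i = 0; i < pix[a].size(); ++i) {
        int p = pix[a][i];
        double ddx = p / H - ax, ddy = p % H - ay;
        double d = ddx * ddx + ddy * ddy;
        if (d < best) {
          best = d;
          start = p;
        }
      }
    }
    ++cur;   // visited
    ++cur2;  // kept
    PixQueue q;
    stamp[start] = cur;
    q.push(QPix{start, best});
    int kept = 0;
    while (!q.empty() && kept < keep) {
      QPix t = q.top();
      q.pop();
      stamp2[t.p] = cur2;
      ++kept;
      int x = t.p / H, y = t.p % H;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dx && !dy) continue;
          int nx = x + dx, ny = y + dy;
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int np = ny + nx * H;
          if (grid[np] == id && stamp[np] != cur) {
            stamp[np] = cur;
            double ddx = nx - ax, ddy = ny - ay;
            q.push(QPix{np, ddx * ddx + ddy * ddy});
          }
        }
      }
    }
    std::vector<int> newpix;
    newpix.reserve(keep);
    double nsx = 0, nsy = 0;
    for (size_t i = 0; i < pix[a].size(); ++i) {
      int p = pix[a][i];
      if (stamp2[p] == cur2) {
        newpix.push_back(p);
        nsx += p / H;
        nsy += p % H;
      } else {
        grid[p] = 0;
        freed.push_back(p);
      }
    }
    occupied -= (int)freed.size();
    pix[a].swap(newpix);
    area[a] = (int)pix[a].size();
    sx[a] = nsx;
    sy[a] = nsy;
    return freed;
  }

  // Grow agent a into adjacent free pixels (nearest to its centroid first)
  // until it reaches target_total pixels or no adjacent free space remains.
  int grow(int a, int target_total) {
    if (area[a] >= target_total) return 0;
    int id = a + 1;
    double ax = cx(a), ay = cy(a);
    ++cur;
    PixQueue q;
    for (size_t i = 0; i < pix[a].size(); ++i) {
      int p = pix[a][i];
      int x = p / H, y = p % H;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dx && !dy) continue;
          int nx = x + dx, ny = y + dy;
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int np = ny + nx * H;
          if (grid[np] == 0 && stamp[np] != cur) {
            stamp[np] = cur;
            double ddx = nx - ax, ddy = ny - ay;
            q.push(QPix{np, ddx * ddx + ddy * ddy});
          }
        }
      }
    }
    int got = 0;
    while (!q.empty() && area[a] < target_total) {
      QPix t = q.top();
      q.pop();
      if (grid[t.p] != 0) continue;
      grid[t.p] = id;
      pix[a].push_back(t.p);
      int x = t.p / H, y = t.p % H;
      sx[a] += x;
      sy[a] += y;
      area[a]++;
      occupied++;
      ++got;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dx && !dy) continue;
          int nx = x + dx, ny = y + dy;
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int np = ny + nx * H;
          if (grid[np] == 0 && stamp[np] != cur) {
            stamp[np] = cur;
            double ddx = nx - ax, ddy = ny - ay;
            q.push(QPix{np, ddx * ddx + ddy * ddy});
          }
        }
      }
    }
    return got;
  }

  // Distinct agents owning pixels 8-adjacent to a's footprint.
  void adjacent_agents(int a, std::vector<int>& out) {
    out.clear();
    int id = a + 1;
    ++cur2;
    for (size_t i = 0; i < pix[a].size(); ++i) {
      int p = pix[a][i];
      int x = p / H, y = p % H;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          if (!dx && !dy) continue;
          int nx = x + dx, ny = y + dy;
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int np = ny + nx * H;
          int oid = grid[np];
          if (oid != 0 && oid != id && stamp2[np] != cur2) {
            stamp2[np] = cur2;
            bool seen = false;
            for (size_t k = 0; k < out.size(); ++k)
              if (out[k] == oid - 1) { seen = true; break; }
            if (!seen) out.push_back(oid - 1);
          }
        }
      }
    }
  }

  void restore(int a, const std::vector<int>& freed) {
    int id = a + 1;
    for (size_t i = 0; i < freed.size(); ++i) {
      int p = freed[i];
      grid[p] = id;
      pix[a].push_back(p);
      sx[a] += p / H;
      sy[a] += p % H;
    }
    area[a] += (int)freed.size();
    occupied += (int)freed.size();
  }

  int append_agent(int cls_, int limit_, int divs_) {
    cls.push_back(cls_);
    st.push_back(0);
    divs.push_back(divs_);
    limit.push_back(limit_);
    phase.push_back(0.0);
    area.push_back(0);
    sx.push_back(0.0);
    sy.push_back(0.0);
    pix.push_back(std::vector<int>());
    return (int)cls.size();  // new id
  }

  // One division attempt for a proliferative agent whose cycle is complete.
  // When reachable free space is short, the divider may compress adjacent
  // proliferative agents toward min_area (contact compression is shared with
  // the neighborhood); senescent footprints are rigid.
  int try_divide(int a) {
    if (limit[a] >= 0 && divs[a] >= limit[a]) {
      st[a] = 1;  // permanent senescent conversion
      return OUT_CONVERTED;
    }
    std::vector<int> frontier1;
    int free = free_area(a, radius, &frontier1);
    bool open = free >= max_area;

    std::vector<int> squeeze;  // squeezable neighbors, largest first
    int slack = 0;
    if (!open) {
      adjacent_agents(a, squeeze);
      size_t k = 0;
      for (size_t i = 0; i < squeeze.size(); ++i) {
        int nb = squeeze[i];
        if (area[nb] > min_area) {  // senescent yield too, but never regrow
          slack += area[nb] - min_area;
          squeeze[k++] = nb;
        }
      }
      squeeze.resize(k);
      for (size_t i = 1; i < squeeze.size(); ++i)  // insertion sort, tiny n
        for (size_t j = i; j > 0 && area[squeeze[j]] > area[squeeze[j - 1]];
             --j)
          std::swap(squeeze[j], squeeze[j - 1]);
    }
    int total = area[a] + free + slack;
    if (total < 2 * min_area) {
      phase[a] = cycle;  // hold completed timer until space appears
      return OUT_BLOCKED;
    }
    int t_d, t_m;
    if (open) {
      t_d = max_area;
      t_m = area[a];
    } else {
      int s = total / 2;
      if (s > max_area) s = max_area;
      t_d = s;
      int rest = total - s;
      if (rest > max_area) rest = max_area;
      t_m = std::min(area[a], std::max(min_area, rest));
    }
    // daughter seed: a random free pixel touching the mother when one
    // exists; the mother then retreats toward her opposite pole so the
    // freed pixels stay connected to the seed side
    int seed = -1;
    if (!frontier1.empty())
      seed =
          frontier1[(int)(unif_rand() * frontier1.size()) % frontier1.size()];
    int pole = -1;
    {
      double ref_x, ref_y;
      if (seed >= 0) {
        ref_x = seed / H;
        ref_y = seed % H;
      } else {
        ref_x = cx(a);
        ref_y = cy(a);
      }
      double best = -1.0;
      for (size_t i = 0; i < pix[a].size(); ++i) {
        int p = pix[a][i];
        double ddx = p / H - ref_x, ddy = p % H - ref_y;
        double d = ddx * ddx + ddy * ddy;
        if (d > best) {
          best = d;
          pole = p;
        }
      }
    }
    std::vector<int> freed = shrink(a, t_m, pole);
    if (seed < 0 && !freed.empty()) {
      // fully enclosed: the daughter germinates in the freed half,
      // farthest from the mother's retained pole
      double px0 = pole / H, py0 = pole % H, best = -1.0;
      for (size_t i = 0; i < freed.size(); ++i) {
        int p = freed[i];
        double ddx = p / H - px0, ddy = p % H - py0;
        double d = ddx * ddx + ddy * ddy;
        if (d > best) {
          best = d;
          seed = p;
        }
      }
    }
    // squeeze neighbors only as far as needed to host the daughter; the
    // ones nearest the daughter seed yield first so the freed pixels stay
    // reachable from it
    std::vector<std::pair<int, std::vector<int> > > squeezed;
    if (!open) {
      if (seed >= 0 && squeeze.size() > 1) {
        double sx0 = seed / H, sy0 = seed % H;
        std::vector<double> dist(squeeze.size());
        for (size_t i = 0; i < squeeze.size(); ++i) {
          double ddx = cx(squeeze[i]) - sx0, ddy = cy(squeeze[i]) - sy0;
          dist[i] = ddx * ddx + ddy * ddy;
        }
        for (size_t i = 1; i < squeeze.size(); ++i)
          for (size_t j = i; j > 0 && dist[j] < dist[j - 1]; --j) {
            std::swap(squeeze[j], squeeze[j - 1]);
            std::swap(dist[j], dist[j - 1]);
          }
      }
      int deficit = t_d - free - (int)freed.size();
      for (size_t i = 0; i < squeeze.size() && deficit > 0; ++i) {
        int nb = squeeze[i];
        int give = std::min(area[nb] - min_area, deficit);
        if (give <= 0) continue;
        std::vector<int> fnb = shrink(nb, area[nb] - give);
        deficit -= (int)fnb.size();
        squeezed.push_back(std::make_pair(nb, fnb));
      }
    }
    if (seed < 0) {
      // no free pixel touched the mother before squeezing; look again now
      frontier1.clear();
      free_area(a, 1, &frontier1);
      if (!frontier1.empty())
        seed = frontier1[(int)(unif_rand() * frontier1.size()) %
                         frontier1.size()];
    }
    int got = 0, d = -1;
    if (seed >= 0 && grid[seed] == 0) {
      d = append_agent(cls[a], limit[a], divs[a] + 1) - 1;
      got = accrete(d, seed, seed / H, seed % H, t_d);
    }
    if (d >= 0 && got > 0 && got < min_area && t_m > min_area) {
      // last resort: the mother retreats to the minimum footprint, freeing
      // pixels on the seed side for the daughter to complete
      std::vector<int> extra = shrink(a, min_area, pole);
      freed.insert(freed.end(), extra.begin(), extra.end());
      got += grow(d, t_d);
    }
    if (got < min_area) {
      if (d >= 0) {
        release_tail(d, got);
        cls.pop_back(); st.pop_back(); divs.pop_back(); limit.pop_back();
        phase.pop_back(); area.pop_back(); sx.pop_back(); sy.pop_back();
        pix.pop_back();
      }
      for (size_t i = squeezed.size(); i-- > 0;)
        restore(squeezed[i].first, squeezed[i].second);
      restore(a, freed);
      phase[a] = cycle;
      return OUT_BLOCKED;
    }
    divs[a] += 1;
    phase[a] = 0.0;
    return (open && got == max_area && t_m == area[a]) ? OUT_DIVIDED
                                                       : OUT_COMPRESSED;
  }

  void counts(int& np, int& ns, int& vp, int& vs) const {
    np = ns = vp = vs = 0;
    for (size_t a = 0; a < cls.size(); ++a) {
      if (cls[a] == 0) {
        if (st[a] == 0) ++np; else ++ns;
      } else {
        if (st[a] == 0) ++vp; else ++vs;
      }
    }
  }

  List export_state(const IntegerMatrix& proto) const {
    IntegerMatrix g(H, W);
    std::copy(grid.begin(), grid.end(), g.begin());
    int n = (int)cls.size();
    IntegerVector cls_(n), st_(n), divs_(n), limit_(n), area_(n);
    NumericVector phase_(n), cx_(n), cy_(n);
    for (int a = 0; a < n; ++a) {
      cls_[a] = cls[a];
      st_[a] = st[a];
      divs_[a] = divs[a];
      limit_[a] = limit[a];
      area_[a] = area[a];
      phase_[a] = phase[a];
      cx_[a] = area[a] > 0 ? sx[a] / area[a] : NA_REAL;
      cy_[a] = area[a] > 0 ? sy[a] / area[a] : NA_REAL;
    }
    return List::create(_["grid"] = g, _["class"] = cls_, _["state"] = st_,
                        _["divisions"] = divs_, _["limit"] = limit_,
                        _["phase"] = phase_, _["area"] = area_,
                        _["cx"] = cx_, _["cy"] = cy_,
                        _["occupied"] = occupied);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_seed_blobs(IntegerMatrix grid, IntegerVector cls, IntegerVector st,
                    IntegerVector divs, IntegerVector limit,
                    NumericVector phase, int blob_area, int max_tries) {
  Engine e;
  e.init_grid(grid);
  int n0 = 0;
  for (int p = 0; p < e.WH; ++p)
    if (e.grid[p] > n0) n0 = e.grid[p];
  if (n0 != 0) stop("cpp_seed_blobs expects an empty grid");
  e.init_agents(cls, st, divs, limit, phase);
  int n = cls.size();
  for (int a = 0; a < n; ++a) {
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      int x = (int)(unif_rand() * e.W) % e.W;
      int y = (int)(unif_rand() * e.H) % e.H;
      int p = y + x * e.H;
      if (e.grid[p] != 0) continue;
      int got = e.accrete(a, p, x, y, blob_area);
      if (got == blob_area) {
        placed = true;
        break;
      }
      e.release_tail(a, got);
    }
    if (!placed) {
      List out = e.export_state(grid);
      out["placed"] = a;  // agents 0..a-1 placed successfully
      return out;
    }
  }
  List out = e.export_state(grid);
  out["placed"] = n;
  return out;
}

// [[Rcpp::export]]
int cpp_free_area(IntegerMatrix grid, IntegerVector cls, IntegerVector st,
                  IntegerVector divs, IntegerVector limit, NumericVector phase,
                  int id, int radius) {
  Engine e;
  e.init_grid(grid);
  e.init_agents(cls, st, divs, limit, phase);
  if (id < 1 || id > (int)e.cls.size() || e.area[id - 1] == 0)
    stop("agent not placed on grid");
  return e.free_area(id - 1, radius);
}

// [[Rcpp::export]]
List cpp_resize(IntegerMatrix grid, IntegerVector cls, IntegerVector st,
                IntegerVector divs, IntegerVector limit, NumericVector phase,
                int id, int target) {
  Engine e;
  e.init_grid(grid);
  e.init_agents(cls, st, divs, limit, phase);
  if (id < 1 || id > (int)e.cls.size() || e.area[id - 1] == 0)
    stop("agent not placed on grid");
  int a = id - 1;
  if (target < e.area[a]) {
    e.shrink(a, target);
  } else if (target > e.area[a]) {
    std::vector<int> frontier1;
    e.free_area(a, 1, &frontier1);
    double ax = e.cx(a), ay = e.cy(a);
    // grow by accreting nearest free pixels to the current centroid
    while (e.area[a] < target && !frontier1.empty()) {
      int bi = 0;
      double best = 1e30;
      for (size_t i = 0; i < frontier1.size(); ++i) {
        int p = frontier1[i];
        double ddx = p / e.H - ax, ddy = p % e.H - ay;
        double d = ddx * ddx + ddy * ddy;
        if (d < best) { best = d; bi = (int)i; }
      }
      int seed = frontier1[bi];
      if (e.accrete(a, seed, ax, ay, 1) == 0) break;
      frontier1.clear();
      e.free_area(a, 1, &frontier1);
    }
  }
  List out = e.export_state(grid);
  out["achieved"] = e.area[a];
  return out;
}

// [[Rcpp::export]]
List cpp_attempt_division(IntegerMatrix grid, IntegerVector cls,
                          IntegerVector st, IntegerVector divs,
                          IntegerVector limit, NumericVector phase, int id,
                          double cycle_hours, int min_area, int max_area,
                          int radius) {
  Engine e;
  e.init_grid(grid);
  e.init_agents(cls, st, divs, limit, phase);
  if (id < 1 || id > (int)e.cls.size() || e.area[id - 1] == 0)
    stop("agent not placed on grid");
  e.cycle = cycle_hours;
  e.min_area = min_area;
  e.max_area = max_area;
  e.radius = radius;
  int outcome = e.try_divide(id - 1);
  List out = e.export_state(grid);
  out["outcome"] = outcome;
  return out;
}

// [[Rcpp::export]]
List cpp_run_passage(IntegerMatrix grid, IntegerVector cls, IntegerVector st,
                     IntegerVector divs, IntegerVector limit,
                     NumericVector phase, double cycle_hours, double dt,
                     int min_area, int max_area, int radius,
                     double trigger_frac, double max_hours, double clock0) {
  Engine e;
  e.init_grid(grid);
  e.init_agents(cls, st, divs, limit, phase);
  e.cycle = cycle_hours;
  e.dtv = dt;
  e.min_area = min_area;
  e.max_area = max_area;
  e.radius = radius;

  double trigger_pixels = trigger_frac * e.WH;
  std::vector<double> rec_t;
  std::vector<int> rec_np, rec_ns, rec_vp, rec_vs, rec_occ, rec_div;
  std::string reason = "timeout";
  double elapsed = 0.0;

  int np, ns, vp, vs;
  e.counts(np, ns, vp, vs);
  if (np + vp == 0) {
    reason = "exhausted";
    max_hours = 0.0;
  } else if (e.occupied >= trigger_pixels && trigger_frac <= 1.0) {
    reason = "confluent";
    max_hours = 0.0;
  }

  std::vector<int> order;
  while (elapsed + dt <= max_hours + 1e-9) {
    int n0 = (int)e.cls.size();
    order.resize(n0);
    for (int i = 0; i < n0; ++i) order[i] = i;
    for (int i = n0 - 1; i > 0; --i) {  // Fisher-Yates with R's RNG
      int j = (int)(unif_rand() * (i + 1)) % (i + 1);
      std::swap(order[i], order[j]);
    }
    int ndiv = 0, nconv = 0;
    bool maturing = false;
    for (int i = 0; i < n0; ++i) {
      int a = order[i];
      if (e.st[a] == 1) continue;
      e.phase[a] += dt;
      if (e.phase[a] >= e.cycle - 1e-9) {
        e.phase[a] = e.cycle;
        int out = e.try_divide(a);
        if (out == OUT_DIVIDED || out == OUT_COMPRESSED) ++ndiv;
        else if (out == OUT_CONVERTED) ++nconv;
      } else {
        maturing = true;
      }
    }
    // re-spreading: compressed proliferative agents regrow into adjacent
    // free space toward the preferred footprint; senescent stay rigid
    int regrown = 0;
    for (int a = 0; a < (int)e.cls.size(); ++a) {
      if (e.st[a] == 0 && e.area[a] < e.max_area)
        regrown += e.grow(a, e.max_area);
    }
    elapsed += dt;
    e.counts(np, ns, vp, vs);
    rec_t.push_back(clock0 + elapsed);
    rec_np.push_back(np);
    rec_ns.push_back(ns);
    rec_vp.push_back(vp);
    rec_vs.push_back(vs);
    rec_occ.push_back(e.occupied);
    rec_div.push_back(ndiv);
    if (e.occupied >= trigger_pixels && trigger_frac <= 1.0) {
      reason = "confluent";
      break;
    }
    if (np + vp == 0) {
      reason = "exhausted";
      break;
    }
    if (!maturing && ndiv == 0 && nconv == 0 && regrown == 0) {
      reason = "stalled";  // every proliferative agent is space-blocked
      break;
    }
  }

  List out = e.export_state(grid);
  out["series"] = DataFrame::create(
      _["time_hours"] = rec_t, _["n_normal_proliferative"] = rec_np,
      _["n_normal_senescent"] = rec_ns, _["n_variant_proliferative"] = rec_vp,
      _["n_variant_senescent"] = rec_vs, _["occupied_pixels"] = rec_occ,
      _["divisions"] = rec_div);
  out["reason"] = reason;
  out["elapsed_hours"] = elapsed;
  return out;
}
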