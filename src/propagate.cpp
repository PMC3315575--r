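// Seeded propagation segmentation: multi-source Dijkstra over the pixel
// grid. One step from pixel p to a neighbour q costs
//   sqrt(lambda * s(p,q)^2 + (I(p) - I(q))^2),
// with s the spatial step length (1 for axial, sqrt(2) for diagonal moves).
// Every reachable foreground pixel takes the label of the seed with minimal
// accumulated path cost; exact cost ties resolve to the smaller seed label
// (enforced by the priority ordering), remaining ties to the smaller pixel
// index, so the labeling is fully deterministic.

#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  double cost;
  int label;
  int pixel;
};

struct NodeGreater {
  bool operator()(const Node& a, const Node& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.label != b.label) return a.label > b.label;
    return a.pixel > b.pixel;
  }
};

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_propagate(NumericMatrix intensity, IntegerMatrix seeds,
                            LogicalMatrix foreground, double lambda,
                            int connectivity) {
  const int H = intensity.nrow(), W = intensity.ncol();
  if (seeds.nrow() != H || seeds.ncol() != W ||
      foreground.nrow() != H || foreground.ncol() != W)
    stop("intensity, seeds and foreground must have identical dimensions");
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");

  const int ndir = (connectivity == 8) ? 8 : 4;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double sqrt2 = std::sqrt(2.0);

  IntegerMatrix labels(H, W);
  std::vector<double> dist(static_cast<size_t>(H) * W,
                           std::numeric_limits<double>::infinity());
  std::vector<bool> settled(static_cast<size_t>(H) * W, false);
  std::priority_queue<Node, std::vector<Node>, NodeGreater> pq;

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int p = c * H + r;
      if (seeds(r, c) > 0) {
        dist[p] = 0.0;
        pq.push(Node{0.0, seeds(r, c), p});
      }
    }
  }

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    const int p = nd.pixel;
    if (settled[p]) continue;
    settled[p] = true;
    const int r = p % H, c = p / H;
    labels(r, c) = nd.label;
    const double ip = intensity(r, c);
    for (int k = 0; k < ndir; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (!foreground(rr, cc)) continue;
      const int q = cc * H + rr;
      if (settled[q]) continue;
      const double s = (k < 4) ? 1.0 : sqrt2;
      const double di = ip - intensity(rr, cc);
      const double w = std::sqrt(lambda * s * s + di * di);
      const double nc = nd.cost + w;
      if (nc < dist[q]) {
        dist[q] = nc;
        pq.push(Node{nc, nd.label, q});
      } else if (nc == dist[q]) {
        // equal-cost alternative: keep the chance to win on a smaller label
        pq.push(Node{nc, nd.label, q});
      }
    }
  }
  return labels;
}
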