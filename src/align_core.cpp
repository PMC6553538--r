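#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <deque>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Minimizer sketching + anchor matching + co-linear chaining for the
// micro-aligner. Sequences arrive as integer codes 0..3 (A,C,G,T); 4 = N.
// k-mers containing N never produce anchors.

// Invertible 64-bit mix (murmur finalizer) so that minimizer selection is not
// biased toward low-complexity lexicographic minima such as poly-A.
static inline uint64_t hash64(uint64_t key, uint64_t mask) {
    key = (~key + (key << 21)) & mask;
    key = key ^ (key >> 24);
    key = ((key + (key << 3)) + (key << 8)) & mask;
    key = key ^ (key >> 14);
    key = ((key + (key << 2)) + (key << 4)) & mask;
    key = key ^ (key >> 28);
    key = (key + (key << 31)) & mask;
    return key;
}

struct Mz { uint64_t h; int pos; };

static void sketch_seq(const IntegerVector& codes, int k, int w,
                       std::vector<Mz>& out) {
    const int n = codes.size();
    if (n < k) return;
    const int m = n - k + 1;
    const uint64_t mask = (2 * k < 64) ? ((1ULL << (2 * k)) - 1) : UINT64_MAX;
    std::vector<uint64_t> h(m, UINT64_MAX);
    uint64_t cur = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
        int c = codes[i];
        if (c >= 0 && c < 4) {
            cur = ((cur << 2) | (uint64_t)c) & mask;
            ++valid;
        } else {
            cur = 0;
            valid = 0;
        }
        if (i >= k - 1 && valid >= k) h[i - k + 1] = hash64(cur, mask);
    }
    // windowed minima over w consecutive k-mer starts (monotone deque)
    if (w < 1) w = 1;
    std::deque<int> dq;
    int last_pos = -1;
    for (int i = 0; i < m; ++i) {
        while (!dq.empty() && h[dq.back()] >= h[i]) dq.pop_back();
        dq.push_back(i);
        while (dq.front() <= i - w) dq.pop_front();
        if (i >= w - 1 || i == m - 1) {
            int p = dq.front();
            if (h[p] != UINT64_MAX && p != last_pos) {
                out.push_back({h[p], p});
                last_pos = p;
            }
        }
    }
}

// [[Rcpp::export(name = ".mz_anchors", rng = false)]]
IntegerMatrix mz_anchors(IntegerVector qcodes, IntegerVector tcodes,
                         int k, int w, int max_occ) {
    std::vector<Mz> qm, tm;
    sketch_seq(qcodes, k, w, qm);
    sketch_seq(tcodes, k, w, tm);
    std::unordered_map<uint64_t, std::vector<int> > tidx;
    tidx.reserve(tm.size() * 2);
    for (const Mz& z : tm) tidx[z.h].push_back(z.pos);
    std::vector<std::pair<int, int> > anchors;
    for (const Mz& z : qm) {
        auto it = tidx.find(z.h);
        if (it == tidx.end()) continue;
        if ((int)it->second.size() > max_occ) continue;  // repetitive seed
        for (int tp : it->second) anchors.push_back({z.pos, tp});
    }
    IntegerMatrix out(anchors.size(), 2);
    for (size_t i = 0; i < anchors.size(); ++i) {
        out(i, 0) = anchors[i].first;
        out(i, 1) = anchors[i].second;
    }
    return out;
}

// Chain anchors by sparse DP: score = sum of non-overlapping anchor coverage
// minus gap penalties |dq - dt|; both per-step gaps bounded by max_gap.
// Returns chains as a list of anchor-index vectors (1-based into the input),
// highest scoring first, each anchor used at most once.
// [[Rcpp::export(name = ".chain_anchors", rng = false)]]
List chain_anchors(IntegerVector qpos, IntegerVector tpos, int k,
                   int max_gap, double min_score, int max_iter) {
    const int n = qpos.size();
    if (n == 0) return List::create();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        if (tpos[a] != tpos[b]) return tpos[a] < tpos[b];
        return qpos[a] < qpos[b];
    });
    std::vector<double> f(n);
    std::vector<int> pre(n, -1);
    for (int ii = 0; ii < n; ++ii) {
        int i = ord[ii];
        f[i] = k;
        int iters = 0;
        for (int jj = ii - 1; jj >= 0; --jj) {
            int j = ord[jj];
            int dt = tpos[i] - tpos[j];
            if (dt > max_gap) break;
            int dq = qpos[i] - qpos[j];
            if (dq <= 0 || dt <= 0 || dq > max_gap) continue;
            if (++iters > max_iter) break;
            double gain = std::min(std::min(dq, dt), k) - std::abs(dq - dt);
            double cand = f[j] + gain;
            if (cand > f[i]) { f[i] = cand; pre[i] = j; }
        }
    }
    // greedy backtracking from best unused ends
    std::vector<int> byscore(n);
    for (int i = 0; i < n; ++i) byscore[i] = i;
    std::sort(byscore.begin(), byscore.end(), [&](int a, int b) {
        if (f[a] != f[b]) return f[a] > f[b];
        if (tpos[a] != tpos[b]) return tpos[a] < tpos[b];
        return qpos[a] < qpos[b];
    });
    std::vector<char> used(n, 0);
    List chains;
    for (int i : byscore) {
        if (used[i] || f[i] < min_score) continue;
        std::vector<int> path;
        int cur = i;
        double base = 0.0;  // score carried by an already-used prefix
        while (cur >= 0) {
            if (used[cur]) { base = f[cur]; break; }
            path.push_back(cur);
            used[cur] = 1;
            cur = pre[cur];
        }
        // a fragment diverging from an extracted chain is scored by its own
        // contribution, not the shared prefix
        double own = f[i] - base;
        if (path.size() < 1 || own < min_score) continue;
        std::reverse(path.begin(), path.end());
        IntegerVector iv(path.size());
        for (size_t j = 0; j < path.size(); ++j) iv[j] = path[j] + 1;
        iv.attr("score") = own;
        chains.push_back(iv);
    }
    return chains;
}
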