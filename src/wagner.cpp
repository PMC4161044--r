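#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Ordered-character (Wagner) parsimony down-pass on a rooted binary tree,
// the interval (Farris) algorithm. For linearly ordered, reversible states
// with cost |i - j| the per-node state-set minimising the subtree cost is a
// contiguous interval; merging two child intervals costs the gap between
// them when they are disjoint, zero otherwise. Equivalent to Sankoff dynamic
// programming with the L1 cost matrix but O(1) per node per character.
//
// kids : (nNodesTotal x 2) child ids per node, 0 for tips / unused slots.
// root : id of the root (must have exactly two children).
// ntip : ids 1..ntip are tips; rows of `states` are indexed by tip id.
// states: (ntip x nchar) integer states, no NAs (checked R-side).
//
// Returns per-character minimal length and the interval of root states that
// attain it (exactly the min-cost root assignments).
// [[Rcpp::export(name = ".wagnerDownPass")]]
List wagner_down_pass(const IntegerMatrix& kids, const int root, const int ntip,
                      const IntegerMatrix& states) {
    const int nNode = kids.nrow();
    const int nChar = states.ncol();
    if (root < 1 || root > nNode)
        stop("invalid root id");

    // iterative postorder over the active subtree
    std::vector<int> post;
    post.reserve(nNode);
    std::vector<int> stk;
    stk.push_back(root);
    while (!stk.empty()) {
        int v = stk.back();
        stk.pop_back();
        post.push_back(v);
        if (v > ntip) {
            int a = kids(v - 1, 0), b = kids(v - 1, 1);
            if (a == 0 || b == 0)
                stop("internal node without two children (tree must be binary)");
            stk.push_back(a);
            stk.push_back(b);
        }
    }
    std::reverse(post.begin(), post.end());

    std::vector<int> lo((size_t) nNode * nChar), hi((size_t) nNode * nChar);
    IntegerVector cost(nChar);

    for (size_t k = 0; k < post.size(); ++k) {
        const int v = post[k];
        const size_t off = (size_t)(v - 1) * nChar;
        if (v <= ntip) {
            for (int c = 0; c < nChar; ++c) {
                const int s = states(v - 1, c);
                lo[off + c] = s;
                hi[off + c] = s;
            }
        } else {
            const int a = kids(v - 1, 0), b = kids(v - 1, 1);
            const size_t offa = (size_t)(a - 1) * nChar;
            const size_t offb = (size_t)(b - 1) * nChar;
            for (int c = 0; c < nChar; ++c) {
                const int la = lo[offa + c], ha = hi[offa + c];
                const int lb = lo[offb + c], hb = hi[offb + c];
                const int nl = std::max(la, lb);
                const int nh = std::min(ha, hb);
                if (nl <= nh) {             // intervals intersect
                    lo[off + c] = nl;
                    hi[off + c] = nh;
                } else {                    // disjoint: pay the gap
                    cost[c] += nl - nh;
                    lo[off + c] = nh;
                    hi[off + c] = nl;
                }
            }
        }
    }

    const size_t offr = (size_t)(root - 1) * nChar;
    IntegerVector rlo(nChar), rhi(nChar);
    for (int c = 0; c < nChar; ++c) {
        rlo[c] = lo[offr + c];
        rhi[c] = hi[offr + c];
    }
    return List::create(_["cost"] = cost, _["lower"] = rlo, _["upper"] = rhi);
}
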