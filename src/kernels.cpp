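// Permutation / split-averaging kernels.
//
// Hot path shared by null-distribution generation and power simulation.
// Mid-rank Mann-Whitney correlations are recomputed per (label, subset)
// pair from a per-gene sample ordering precomputed once per dataset
// (O(genes * samples) per evaluation instead of a fresh sort), which is
// mathematically identical to ranking from scratch.  Genes without tied
// expression values (the typical case for continuous data) take a
// branch-light integer path; tied genes fall back to explicit mid-rank
// runs.  The two halves of a split are scored in a single pass.  All
// randomness is drawn from R's RNG so set.seed() governs every draw.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Fisher-Yates shuffle using R's RNG
static void shuffle_rng(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(v[i], v[j]);
    }
}

// dataset laid out for the inner loops: per-gene sample order (ascending
// expression) contiguous per gene, matching sorted values, per-gene tie
// flag
struct Prep {
    int G, N;
    std::vector<int> ordT;      // G blocks of N sample indices (0-based)
    std::vector<double> xsT;    // matching sorted values
    std::vector<char> hasTies;
};

static Prep make_prep(const IntegerMatrix& ord, const NumericMatrix& xs) {
    Prep P;
    P.G = ord.nrow(); P.N = ord.ncol();
    if (xs.nrow() != P.G || xs.ncol() != P.N)
        stop("ord and xs dimensions differ");
    P.ordT.resize((size_t)P.G * P.N);
    P.xsT.resize((size_t)P.G * P.N);
    P.hasTies.assign(P.G, 0);
    for (int g = 0; g < P.G; ++g) {
        int* po = &P.ordT[(size_t)g * P.N];
        double* pv = &P.xsT[(size_t)g * P.N];
        for (int k = 0; k < P.N; ++k) {
            int j = ord(g, k) - 1;
            if (j < 0 || j >= P.N) stop("ord entries must be 1..N");
            po[k] = j;
            pv[k] = xs(g, k);
            if (k > 0 && pv[k] == pv[k - 1]) P.hasTies[g] = 1;
            if (k > 0 && pv[k] < pv[k - 1])
                stop("xs rows must be sorted ascending");
        }
    }
    return P;
}

static inline double mw_corr(double RA, int nA, int nB) {
    const double U = RA - 0.5 * nA * (nA + 1);
    return 2.0 * U / ((double)nA * nB) - 1.0;
}

// correlations for both halves of a split in one pass; sub1[j] in {0,1},
// half 2 is its complement
// r values of a rank statistic lie on the grid (2U)/(nA*nB) - 1 with
// 2U an integer in 0..2*nA*nB; the corr_* functions emit that integer key
// alongside r so the per-evaluation gene sort can be a counting sort.
static void corr_split(const Prep& P, const std::vector<int>& grpA,
                       const std::vector<char>& sub1,
                       std::vector<double>& r1, std::vector<double>& r2,
                       std::vector<int>& key1, std::vector<int>& key2,
                       int& maxKey1, int& maxKey2) {
    const int N = P.N;
    for (int g = 0; g < P.G; ++g) {
        const int* po = &P.ordT[(size_t)g * N];
        int nA1 = 0, nA2 = 0, m1 = 0, m2 = 0;
        double RA1 = 0, RA2 = 0;
        if (!P.hasTies[g]) {
            for (int k = 0; k < N; ++k) {
                const int j = po[k];
                const int s = sub1[j], a = grpA[j];
                m1 += s; m2 += 1 - s;
                const int a1 = a & s, a2 = a & (1 - s);
                RA1 += a1 * m1; nA1 += a1;
                RA2 += a2 * m2; nA2 += a2;
            }
        } else {
            const double* pv = &P.xsT[(size_t)g * N];
            int k = 0;
            while (k < N) {
                int e = k;
                while (e < N && pv[e] == pv[k]) ++e;
                // run [k, e): mid-ranks computed per half
                int t1 = 0, t2 = 0, ta1 = 0, ta2 = 0;
                for (int q = k; q < e; ++q) {
                    const int j = po[q];
                    const int s = sub1[j], a = grpA[j];
                    t1 += s; t2 += 1 - s;
                    ta1 += a & s; ta2 += a & (1 - s);
                }
                RA1 += ta1 * (m1 + 0.5 * (t1 + 1));
                RA2 += ta2 * (m2 + 0.5 * (t2 + 1));
                m1 += t1; m2 += t2; nA1 += ta1; nA2 += ta2;
                k = e;
            }
        }
        if (nA1 == 0 || nA1 == m1 || nA2 == 0 || nA2 == m2)
            stop("a sample subset lost a phenotype class entirely");
        r1[g] = mw_corr(RA1, nA1, m1 - nA1);
        r2[g] = mw_corr(RA2, nA2, m2 - nA2);
        key1[g] = (int)std::llround(2.0 * RA1) - nA1 * (nA1 + 1);
        key2[g] = (int)std::llround(2.0 * RA2) - nA2 * (nA2 + 1);
        maxKey1 = 2 * nA1 * (m1 - nA1);
        maxKey2 = 2 * nA2 * (m2 - nA2);
    }
}

// correlations on the full cohort
static void corr_full(const Prep& P, const std::vector<int>& grpA,
                      std::vector<double>& r,
                      std::vector<int>& key, int& maxKey) {
    const int N = P.N;
    for (int g = 0; g < P.G; ++g) {
        const int* po = &P.ordT[(size_t)g * N];
        int nA = 0;
        double RA = 0;
        if (!P.hasTies[g]) {
            for (int k = 0; k < N; ++k) {
                const int a = grpA[po[k]];
                RA += a * (k + 1); nA += a;
            }
        } else {
            const double* pv = &P.xsT[(size_t)g * N];
            int k = 0;
            while (k < N) {
                int e = k;
                while (e < N && pv[e] == pv[k]) ++e;
                int ta = 0;
                for (int q = k; q < e; ++q) ta += grpA[po[q]];
                RA += ta * (k + 0.5 * (e - k + 1));
                nA += ta;
                k = e;
            }
        }
        if (nA == 0 || nA == N)
            stop("a sample subset lost a phenotype class entirely");
        r[g] = mw_corr(RA, nA, N - nA);
        key[g] = (int)std::llround(2.0 * RA) - nA * (nA + 1);
        maxKey = 2 * nA * (N - nA);
    }
}

// correlations on an arbitrary subset (exposed for re-use from R)
static void corr_subset(const Prep& P, const std::vector<int>& grpA,
                        const std::vector<char>& sub,
                        std::vector<double>& r) {
    const int N = P.N;
    for (int g = 0; g < P.G; ++g) {
        const int* po = &P.ordT[(size_t)g * N];
        const double* pv = &P.xsT[(size_t)g * N];
        int m = 0, nA = 0;
        double RA = 0;
        int k = 0;
        while (k < N) {
            int e = k;
            while (e < N && pv[e] == pv[k]) ++e;
            int t = 0, ta = 0;
            for (int q = k; q < e; ++q) {
                const int j = po[q];
                if (sub[j]) { ++t; ta += grpA[j]; }
            }
            RA += ta * (m + 0.5 * (t + 1));
            m += t; nA += ta;
            k = e;
        }
        if (nA == 0 || nA == m)
            stop("a sample subset lost a phenotype class entirely");
        r[g] = mw_corr(RA, nA, m - nA);
    }
}

struct RankedGene { double r; int idx; };

// rank genes by descending r (ties: ascending index) into idxbuf; when an
// integer key grid is available a counting sort is used
static void rank_order(const std::vector<double>& r,
                       const std::vector<int>* key, int maxKey,
                       std::vector<RankedGene>& buf,
                       std::vector<int>& counts, std::vector<int>& idxbuf) {
    const int G = (int)r.size();
    if (key) {
        counts.assign(maxKey + 1, 0);
        for (int g = 0; g < G; ++g) ++counts[(*key)[g]];
        int pos = 0;
        for (int k = maxKey; k >= 0; --k) {   // descending key order
            const int c = counts[k];
            counts[k] = pos;
            pos += c;
        }
        for (int g = 0; g < G; ++g)           // stable: ascending index
            idxbuf[counts[(*key)[g]]++] = g;
    } else {
        for (int g = 0; g < G; ++g) { buf[g].r = r[g]; buf[g].idx = g; }
        std::sort(buf.begin(), buf.end(),
                  [](const RankedGene& a, const RankedGene& b) {
                      return a.r > b.r || (a.r == b.r && a.idx < b.idx);
                  });
        for (int g = 0; g < G; ++g) idxbuf[g] = buf[g].idx;
    }
}

// enrichment score per set for one correlation vector
static void es_all_sets(const std::vector<double>& r,
                        const std::vector<std::vector<int> >& setIdx,
                        const std::vector<std::vector<char> >& mask,
                        double wexp, const std::vector<int>& idxbuf,
                        std::vector<double>& es) {
    const int G = (int)r.size();
    const bool plain = (wexp == 1.0);
    for (size_t s = 0; s < setIdx.size(); ++s) {
        double NR = 0.0;
        for (int gi : setIdx[s])
            NR += plain ? std::fabs(r[gi]) : std::pow(std::fabs(r[gi]), wexp);
        if (NR == 0.0)
            stop("all in-set correlations are zero (N_R = 0)");
        const double miss = 1.0 / (G - (int)setIdx[s].size());
        const char* mk = mask[s].data();
        double cs = 0.0, best = 0.0, besta = -1.0;
        for (int k = 0; k < G; ++k) {
            const int g = idxbuf[k];
            cs += mk[g] ? (plain ? std::fabs(r[g])
                                 : std::pow(std::fabs(r[g]), wexp)) / NR
                        : -miss;
            const double a = std::fabs(cs);
            if (a > besta) { besta = a; best = cs; }
        }
        es[s] = best;
    }
}

// stratified half-split: classes divided as evenly as possible; when both
// class counts are odd the two extras go to opposite halves (one random
// draw decides which side gets which)
static void stratified_split(const std::vector<int>& grpA,
                             std::vector<int>& cls0, std::vector<int>& cls1,
                             std::vector<char>& sub1) {
    const int N = (int)grpA.size();
    cls0.clear(); cls1.clear();
    for (int j = 0; j < N; ++j)
        (grpA[j] ? cls1 : cls0).push_back(j);
    shuffle_rng(cls0);
    shuffle_rng(cls1);
    int take0 = (int)cls0.size() / 2, take1 = (int)cls1.size() / 2;
    const bool odd0 = cls0.size() % 2, odd1 = cls1.size() % 2;
    if (odd0 && odd1) {
        if (unif_rand() < 0.5) ++take0; else ++take1;
    } else if (odd0) {
        if (unif_rand() < 0.5) ++take0;
    } else if (odd1) {
        if (unif_rand() < 0.5) ++take1;
    }
    std::fill(sub1.begin(), sub1.end(), 0);
    for (int t = 0; t < take0; ++t) sub1[cls0[t]] = 1;
    for (int t = 0; t < take1; ++t) sub1[cls1[t]] = 1;
}

static void unpack_sets(const List& sets, int G,
                        std::vector<std::vector<int> >& setIdx,
                        std::vector<std::vector<char> >& mask) {
    const int S = sets.size();
    setIdx.resize(S);
    mask.assign(S, std::vector<char>(G, 0));
    for (int s = 0; s < S; ++s) {
        IntegerVector v = sets[s];            // 0-based indices
        setIdx[s].assign(v.begin(), v.end());
        if (setIdx[s].empty()) stop("empty gene set");
        for (int gi : setIdx[s]) {
            if (gi < 0 || gi >= G) stop("gene set index out of range");
            mask[s][gi] = 1;
        }
    }
}

// Draws of an enrichment statistic for a list of gene sets.
//   M = 0  -> ES on the whole cohort;
//   M >= 1 -> <ES_avg> over M fresh stratified half-splits per draw
//             (M = 1 is ES_avg).
// shuffle = true permutes phenotype labels before each draw (null
// distribution); false keeps the observed labels (for M >= 1 each draw
// still consumes fresh splits: the split-sampling distribution).
// Returns an nDraws x nSets matrix.
// [[Rcpp::export(name = ".statKernel")]]
NumericMatrix statKernel(IntegerMatrix ord, NumericMatrix xs,
                         IntegerVector grpA, List sets, double wexp,
                         int nDraws, int M, bool shuffle) {
    Prep P = make_prep(ord, xs);
    if ((int)grpA.size() != P.N)
        stop("label length does not match sample count");
    std::vector<std::vector<int> > setIdx;
    std::vector<std::vector<char> > mask;
    unpack_sets(sets, P.G, setIdx, mask);
    const int S = (int)setIdx.size();

    std::vector<int> labels0(grpA.begin(), grpA.end());
    std::vector<int> labels(P.N), sampleIdx(P.N), cls0, cls1;
    std::vector<char> sub1(P.N);
    std::vector<double> r(P.G), r2(P.G), es(S), es2(S), acc(S);
    std::vector<int> key(P.G), key2(P.G), counts, idxbuf(P.G);
    std::vector<RankedGene> buf(P.G);
    int maxKey = 0, maxKey2 = 0;

    NumericMatrix out(nDraws, S);
    for (int d = 0; d < nDraws; ++d) {
        if (shuffle) {
            std::iota(sampleIdx.begin(), sampleIdx.end(), 0);
            shuffle_rng(sampleIdx);
            for (int j = 0; j < P.N; ++j)
                labels[j] = labels0[sampleIdx[j]];
        } else {
            labels = labels0;
        }
        if (M == 0) {
            corr_full(P, labels, r, key, maxKey);
            rank_order(r, &key, maxKey, buf, counts, idxbuf);
            es_all_sets(r, setIdx, mask, wexp, idxbuf, es);
            for (int s = 0; s < S; ++s) out(d, s) = es[s];
        } else {
            std::fill(acc.begin(), acc.end(), 0.0);
            for (int m = 0; m < M; ++m) {
                stratified_split(labels, cls0, cls1, sub1);
                corr_split(P, labels, sub1, r, r2, key, key2,
                           maxKey, maxKey2);
                rank_order(r, &key, maxKey, buf, counts, idxbuf);
                es_all_sets(r, setIdx, mask, wexp, idxbuf, es);
                rank_order(r2, &key2, maxKey2, buf, counts, idxbuf);
                es_all_sets(r2, setIdx, mask, wexp, idxbuf, es2);
                for (int s = 0; s < S; ++s)
                    acc[s] += 0.5 * (es[s] + es2[s]);
            }
            for (int s = 0; s < S; ++s) out(d, s) = acc[s] / M;
        }
        if ((d & 255) == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Per-gene scaled Mann-Whitney correlations on a sample subset (0/1).
// [[Rcpp::export(name = ".rankCorrKernel")]]
NumericVector rankCorrKernel(IntegerMatrix ord, NumericMatrix xs,
                             IntegerVector grpA, IntegerVector subset) {
    Prep P = make_prep(ord, xs);
    if ((int)grpA.size() != P.N || (int)subset.size() != P.N)
        stop("dimension mismatch");
    std::vector<int> labels(grpA.begin(), grpA.end());
    std::vector<char> sub(subset.begin(), subset.end());
    std::vector<double> r(P.G);
    corr_subset(P, labels, sub, r);
    return NumericVector(r.begin(), r.end());
}

// Enrichment scores of each set for one correlation vector.
// [[Rcpp::export(name = ".esKernel")]]
NumericVector esKernel(NumericVector rv, List sets, double wexp) {
    const int G = rv.size();
    std::vector<std::vector<int> > setIdx;
    std::vector<std::vector<char> > mask;
    unpack_sets(sets, G, setIdx, mask);
    std::vector<double> r(rv.begin(), rv.end());
    std::vector<RankedGene> buf(G);
    std::vector<int> counts, idxbuf(G);
    std::vector<double> es(setIdx.size());
    rank_order(r, nullptr, 0, buf, counts, idxbuf);   // comparison sort
    es_all_sets(r, setIdx, mask, wexp, idxbuf, es);
    return NumericVector(es.begin(), es.end());
}
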