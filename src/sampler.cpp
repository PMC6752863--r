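#include <Rcpp.h>
#include <random>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

// Inside partition function over nested structures of a simple pair-energy
// model: Z(i,j) sums exp(-E/kT) over all structures of the subsequence i..j,
// where E is the sum of pair energies. Spans shorter than two bases (j < i)
// contribute the empty structure only, Z = 1.
//
// Recurrence (0-based, j unpaired vs. j paired to some k):
//   Z(i,j) = Z(i,j-1) + sum_{k = i .. j-m-1, (k,j) pairable}
//            Z(i,k-1) * exp(-e(k,j)/kT) * Z(k+1,j-1)
// with m = minimum hairpin (unpaired span enclosed by a pair).

static inline double zat(const NumericMatrix& Z, int i, int j) {
    if (j < i) return 1.0;
    return Z(i, j);
}

// [[Rcpp::export(name = ".partitionMatrixCpp")]]
NumericMatrix partitionMatrixCpp(IntegerVector seq, NumericMatrix energy,
                                 double kT, int minHairpin) {
    const int n = seq.size();
    NumericMatrix Z(n, n);
    for (int i = 0; i < n; ++i) Z(i, i) = 1.0;
    for (int len = 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            double z = zat(Z, i, j - 1);
            for (int k = i; k <= j - minHairpin - 1; ++k) {
                double e = energy(seq[k], seq[j]);
                if (e == 0.0) continue;
                z += zat(Z, i, k - 1) * std::exp(-e / kT) * zat(Z, k + 1, j - 1);
            }
            Z(i, j) = z;
        }
    }
    return Z;
}

// Draw one structure with probability exp(-E/kT)/Z by descending the
// recurrence, choosing each branch proportional to its contribution.
static void traceback_one(const IntegerVector& seq, const NumericMatrix& Z,
                          const NumericMatrix& energy, double kT,
                          int minHairpin, std::mt19937_64& rng,
                          std::string& db) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, (int)seq.size() - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j < i) continue;
        double u = unif(rng) * zat(Z, i, j);
        double acc = zat(Z, i, j - 1);
        if (u <= acc) {
            // j unpaired
            stack.push_back(std::make_pair(i, j - 1));
            continue;
        }
        int chosen = -1;
        for (int k = i; k <= j - minHairpin - 1; ++k) {
            double e = energy(seq[k], seq[j]);
            if (e == 0.0) continue;
            acc += zat(Z, i, k - 1) * std::exp(-e / kT) * zat(Z, k + 1, j - 1);
            if (u <= acc) { chosen = k; break; }
        }
        if (chosen < 0) {
            // numerical slack: fall back to the last pairable k
            for (int k = j - minHairpin - 1; k >= i; --k) {
                if (energy(seq[k], seq[j]) != 0.0) { chosen = k; break; }
            }
            if (chosen < 0) { stack.push_back(std::make_pair(i, j - 1)); continue; }
        }
        db[chosen] = '(';
        db[j] = ')';
        stack.push_back(std::make_pair(i, chosen - 1));
        stack.push_back(std::make_pair(chosen + 1, j - 1));
    }
}

// [[Rcpp::export(name = ".sampleStructuresCpp")]]
CharacterVector sampleStructuresCpp(IntegerVector seq, NumericMatrix energy,
                                    double kT, int minHairpin, int n,
                                    double seed) {
    const int len = seq.size();
    NumericMatrix Z = partitionMatrixCpp(seq, energy, kT, minHairpin);
    std::mt19937_64 rng((uint64_t)seed);
    CharacterVector out(n);
    for (int s = 0; s < n; ++s) {
        std::string db(len, '.');
        traceback_one(seq, Z, energy, kT, minHairpin, rng, db);
        out[s] = db;
    }
    return out;
}

// Loop-decomposition context annotation of dot-bracket strings.
// Paired -> P; an unpaired base takes the class of the loop closed by its
// innermost enclosing pair: 0 child pairs -> H, 1 -> I, >=2 -> M; no
// enclosing pair -> E.
// [[Rcpp::export(name = ".annotateContextsCpp")]]
CharacterVector annotateContextsCpp(CharacterVector dbs) {
    const int nseq = dbs.size();
    CharacterVector out(nseq);
    for (int q = 0; q < nseq; ++q) {
        std::string db = as<std::string>(dbs[q]);
        const int n = db.size();
        std::string ctx(n, 'E');
        std::vector<int> stack;
        std::vector<int> nchild(n, 0);
        std::vector<int> encl(n, -1);
        for (int i = 0; i < n; ++i) {
            char c = db[i];
            if (c == '(') {
                if (!stack.empty()) nchild[stack.back()]++;
                stack.push_back(i);
                ctx[i] = 'P';
            } else if (c == ')') {
                if (stack.empty())
                    stop("unbalanced dot-bracket: unmatched ')' at position %d",
                         i + 1);
                stack.pop_back();
                ctx[i] = 'P';
            } else if (c == '.') {
                if (!stack.empty()) encl[i] = stack.back();
            } else {
                stop("invalid dot-bracket character at position %d", i + 1);
            }
        }
        if (!stack.empty())
            stop("unbalanced dot-bracket: unmatched '(' at position %d",
                 stack.back() + 1);
        for (int i = 0; i < n; ++i) {
            if (ctx[i] == 'E' && encl[i] >= 0) {
                int k = nchild[encl[i]];
                ctx[i] = (k == 0) ? 'H' : (k == 1) ? 'I' : 'M';
            }
        }
        out[q] = ctx;
    }
    return out;
}

// Gather/scatter kernels for the same-length 1-D convolution, expressed as
// an im2col matrix product. `idx` is n x width; entry r,w is the 1-based
// source row feeding output row r at kernel offset w, or 0 for the implicit
// zero padding outside the sequence.
// [[Rcpp::export(name = ".im2colCpp")]]
NumericMatrix im2colCpp(NumericMatrix X, IntegerMatrix idx) {
    const int n = X.nrow(), C = X.ncol(), width = idx.ncol();
    NumericMatrix out(n, width * C);
    for (int w = 0; w < width; ++w) {
        for (int c = 0; c < C; ++c) {
            const double* src = &X(0, c);
            double* dst = &out(0, w * C + c);
            const int* id = &idx(0, w);
            for (int r = 0; r < n; ++r) {
                dst[r] = id[r] ? src[id[r] - 1] : 0.0;
            }
        }
    }
    return out;
}

// [[Rcpp::export(name = ".col2imCpp")]]
NumericMatrix col2imCpp(NumericMatrix dXcol, IntegerMatrix idx, int C) {
    const int n = dXcol.nrow(), width = idx.ncol();
    NumericMatrix out(n, C);
    for (int w = 0; w < width; ++w) {
        for (int c = 0; c < C; ++c) {
            const double* src = &dXcol(0, w * C + c);
            double* dst = &out(0, c);
            const int* id = &idx(0, w);
            for (int r = 0; r < n; ++r) {
                if (id[r]) dst[id[r] - 1] += src[r];
            }
        }
    }
    return out;
}

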