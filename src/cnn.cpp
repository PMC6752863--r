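// Fused forward/backward pass of the base convolutional predictor:
// nLayers blocks of (same-length 1-D convolution -> batch normalization ->
// ReLU), then a fully-connected head to one scalar per example. Inputs are
// row-grouped by example (row = pos + b*l), so each convolution is an
// im2col gather followed by one BLAS product. Mirrors the reference
// semantics checked by the finite-difference gradient test.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

static arma::mat gather(const arma::mat& X, const arma::imat& idx) {
    const arma::uword n = X.n_rows, C = X.n_cols, width = idx.n_cols;
    arma::mat out(n, width * C);
    for (arma::uword w = 0; w < width; ++w) {
        for (arma::uword c = 0; c < C; ++c) {
            const double* src = X.colptr(c);
            double* dst = out.colptr(w * C + c);
            const int* id = idx.colptr(w);
            for (arma::uword r = 0; r < n; ++r)
                dst[r] = id[r] ? src[id[r] - 1] : 0.0;
        }
    }
    return out;
}

static arma::mat scatter(const arma::mat& dXcol, const arma::imat& idx,
                         arma::uword C) {
    const arma::uword n = dXcol.n_rows, width = idx.n_cols;
    arma::mat out(n, C, arma::fill::zeros);
    for (arma::uword w = 0; w < width; ++w) {
        for (arma::uword c = 0; c < C; ++c) {
            const double* src = dXcol.colptr(w * C + c);
            double* dst = out.colptr(c);
            const int* id = idx.colptr(w);
            for (arma::uword r = 0; r < n; ++r)
                if (id[r]) dst[id[r] - 1] += src[r];
        }
    }
    return out;
}

// [[Rcpp::export(name = ".cnnLossGradCpp")]]
List cnnLossGradCpp(const arma::mat& X0, const arma::imat& idx,
                    const List& convW, const List& convB,
                    const List& gamma, const List& beta,
                    const List& runMean, const List& runVar,
                    const arma::vec& fcW, double fcb,
                    int B, int l, bool training,
                    const arma::vec& y, bool computeGrads) {
    const int L = convW.size();
    const arma::uword n = X0.n_rows;
    std::vector<arma::mat> Xcols(L), xhats(L), masks(L);
    std::vector<arma::rowvec> invstds(L);
    std::vector<arma::uword> cins(L);
    List newMean(L), newVar(L);
    arma::mat X = X0;
    for (int ly = 0; ly < L; ++ly) {
        arma::mat W = as<arma::mat>(convW[ly]);
        arma::rowvec b = as<arma::rowvec>(convB[ly]);
        arma::rowvec gam = as<arma::rowvec>(gamma[ly]);
        arma::rowvec bet = as<arma::rowvec>(beta[ly]);
        cins[ly] = X.n_cols;
        arma::mat Xcol = gather(X, idx);
        arma::mat Y = Xcol * W;
        Y.each_row() += b;
        arma::rowvec mu, vr;
        if (training) {
            mu = arma::mean(Y, 0);
            vr = arma::mean(arma::square(Y), 0) - arma::square(mu);
            vr.transform([](double v) { return v < 0 ? 0.0 : v; });
            arma::rowvec rm = as<arma::rowvec>(runMean[ly]);
            arma::rowvec rv = as<arma::rowvec>(runVar[ly]);
            newMean[ly] = (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu;
            newVar[ly] = (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * vr;
        } else {
            mu = as<arma::rowvec>(runMean[ly]);
            vr = as<arma::rowvec>(runVar[ly]);
            newMean[ly] = runMean[ly];
            newVar[ly] = runVar[ly];
        }
        arma::rowvec invstd = 1.0 / arma::sqrt(vr + BN_EPS);
        Y.each_row() -= mu;
        Y.each_row() %= invstd;            // Y is now xhat
        arma::mat act = Y;
        act.each_row() %= gam;
        act.each_row() += bet;
        arma::mat mask = arma::conv_to<arma::mat>::from(act > 0);
        X = act % mask;
        if (computeGrads) {
            Xcols[ly] = std::move(Xcol);
            xhats[ly] = std::move(Y);
            masks[ly] = std::move(mask);
            invstds[ly] = invstd;
        }
    }
    const int K = X.n_cols;
    // flatten to B x (l*K): Fm(b, pos + c*l) = X(pos + b*l, c)
    arma::mat Fm(B, l * K);
    for (int c = 0; c < K; ++c)
        for (int b = 0; b < B; ++b)
            for (int p = 0; p < l; ++p)
                Fm(b, p + c * l) = X(p + b * l, c);
    arma::vec pred = Fm * fcW + fcb;

    double loss = 0.0;
    arma::vec dpred(B);
    for (int b = 0; b < B; ++b) {
        double r = pred[b] - y[b];
        if (std::fabs(r) <= 1) {
            loss += 0.5 * r * r;
            dpred[b] = r;
        } else {
            loss += std::fabs(r) - 0.5;
            dpred[b] = r > 0 ? 1.0 : -1.0;
        }
    }
    loss /= B;
    dpred /= B;

    if (!computeGrads)
        return List::create(_["pred"] = pred, _["loss"] = loss,
                            _["runMean"] = newMean, _["runVar"] = newVar);

    List gConvW(L), gConvB(L), gGamma(L), gBeta(L);
    arma::vec gFcW = Fm.t() * dpred;
    double gFcb = arma::accu(dpred);
    arma::mat dFm = dpred * fcW.t();
    arma::mat dX(n, K);
    for (int c = 0; c < K; ++c)
        for (int b = 0; b < B; ++b)
            for (int p = 0; p < l; ++p)
                dX(p + b * l, c) = dFm(b, p + c * l);
    for (int ly = L - 1; ly >= 0; --ly) {
        arma::mat W = as<arma::mat>(convW[ly]);
        arma::rowvec gam = as<arma::rowvec>(gamma[ly]);
        arma::mat dAct = dX % masks[ly];
        gGamma[ly] = arma::rowvec(arma::sum(dAct % xhats[ly], 0));
        gBeta[ly] = arma::rowvec(arma::sum(dAct, 0));
        arma::mat dxhat = dAct;
        dxhat.each_row() %= gam;
        arma::rowvec s1 = arma::sum(dxhat, 0);
        arma::rowvec s2 = arma::sum(dxhat % xhats[ly], 0);
        arma::mat dY = dxhat * (double)n;
        dY.each_row() -= s1;
        dY -= xhats[ly].each_row() % s2;
        dY.each_row() %= invstds[ly] / (double)n;
        gConvW[ly] = Xcols[ly].t() * dY;
        gConvB[ly] = arma::rowvec(arma::sum(dY, 0));
        arma::mat dXcol = dY * W.t();
        dX = scatter(dXcol, idx, cins[ly]);
    }
    return List::create(_["pred"] = pred, _["loss"] = loss,
                        _["runMean"] = newMean, _["runVar"] = newVar,
                        _["dX0"] = dX, _["gConvW"] = gConvW,
                        _["gConvB"] = gConvB, _["gGamma"] = gGamma,
                        _["gBeta"] = gBeta, _["gFcW"] = gFcW,
                        _["gFcb"] = gFcb);
}
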