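// Mask-optimization kernel for PGLCN explanations.
//
// Given a frozen model, optimizes a symmetric edge-mask logit matrix M
// (supported on the instance adjacency, self-loops included) and a
// per-column feature-mask logit vector F by Adam, minimizing
//   -log P(target | masked graph, X * sigmoid(F))
//   + th_ee * mean(binary entropy(sigmoid(M)))   [support entries]
//   + th_fe * mean(binary entropy(sigmoid(F)))
//   + th_es * mean(sigmoid(M))                   [support entries]
//   + th_fs * mean(sigmoid(F))
//
// The conv stack has arbitrary depth; in transductive mode the last
// convolution emits per-node logits, in cohort mode all convolutions are
// ReLU-activated and a two-layer fully connected head follows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Model {
  mat P, Wf1, Wf2;
  rowvec a, bf1, bf2;
  std::vector<mat> W;
  std::vector<rowvec> b;
  bool has_fc;
  bool abs_diff;
};

struct Forward {
  mat sigM, Em, Gt, U, EX, S, Suse, Xs;
  std::vector<mat> Hin, M, Upre;  // per conv layer
  vec srow;
  rowvec f1pre, f1, z, prob;
  rowvec vflat;
  double nll;
};

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }
inline mat relu_m(const mat& x) { return (x + abs(x)) / 2.0; }

Model read_model(const Rcpp::List& params, bool has_fc, bool abs_diff) {
  Model md;
  md.P = Rcpp::as<mat>(params["P"]);
  md.a = Rcpp::as<rowvec>(params["a"]);
  for (int k = 1;; ++k) {
    std::string wn = "Wc" + std::to_string(k);
    if (!params.containsElementNamed(wn.c_str())) break;
    md.W.push_back(Rcpp::as<mat>(params[wn]));
    md.b.push_back(Rcpp::as<rowvec>(params["bc" + std::to_string(k)]));
  }
  md.has_fc = has_fc;
  md.abs_diff = abs_diff;
  if (has_fc) {
    md.Wf1 = Rcpp::as<mat>(params["Wf1"]);
    md.bf1 = Rcpp::as<rowvec>(params["bf1"]);
    md.Wf2 = Rcpp::as<mat>(params["Wf2"]);
    md.bf2 = Rcpp::as<rowvec>(params["bf2"]);
  }
  return md;
}

// Forward pass; fills `fw`.
// renormalize = true: the masked adjacency A * sigmoid(M) enters the
// graph-learning softmax (rows re-normalize around the mask).
// renormalize = false: S is learned from the unmasked graph and the mask
// scales the propagation weights directly (S * sigmoid(M)), so each
// edge's message is attenuated absolutely (mask-explainer convention).
void forward_pass(const mat& X, const mat& A, const Model& md,
                  const mat& Mlog, const vec& Flog,
                  int target_node, int target_class, bool renormalize,
                  Forward& fw) {
  const uword nv = X.n_rows;
  const size_t K = md.W.size();
  fw.sigM = sigm(Mlog);
  fw.Em = renormalize ? mat(A % fw.sigM) : A;
  vec sigF = 1.0 / (1.0 + exp(-Flog));
  fw.Xs = X.each_row() % sigF.t();

  fw.Gt = fw.Xs * md.P;
  fw.U.zeros(nv, nv);
  for (uword k = 0; k < md.P.n_cols; ++k) {
    mat D = repmat(fw.Gt.col(k), 1, nv) - repmat(fw.Gt.col(k).t(), nv, 1);
    fw.U += md.a(k) * (md.abs_diff ? abs(D) : D);
  }
  fw.EX = exp(clamp(fw.U, 0.0, 60.0));
  mat E = fw.Em % fw.EX;
  fw.srow = sum(E, 1) + 1e-12;
  fw.S = E;
  fw.S.each_col() /= fw.srow;
  fw.Suse = renormalize ? fw.S : mat(fw.S % fw.sigM);

  fw.Hin.assign(K, mat());
  fw.M.assign(K, mat());
  fw.Upre.assign(K, mat());
  mat H = fw.Xs;
  for (size_t k = 0; k < K; ++k) {
    fw.Hin[k] = H;
    fw.M[k] = H * md.W[k];
    fw.Upre[k] = fw.Suse * fw.M[k];
    fw.Upre[k].each_row() += md.b[k];
    bool last_logits = !md.has_fc && k == K - 1;
    H = last_logits ? fw.Upre[k] : relu_m(fw.Upre[k]);
  }

  if (!md.has_fc) {
    fw.z = H.row(target_node);
  } else {
    // flatten in node order, channel fastest
    fw.vflat = vectorise(H.t()).t();
    fw.f1pre = fw.vflat * md.Wf1 + md.bf1;
    fw.f1 = relu_m(fw.f1pre);
    fw.z = fw.f1 * md.Wf2 + md.bf2;
  }
  rowvec zs = fw.z - fw.z.max();
  rowvec e = exp(zs);
  fw.prob = e / accu(e);
  double pr = std::min(std::max(fw.prob(target_class), 1e-12), 1.0 - 1e-12);
  fw.nll = -std::log(pr);
}

} // namespace

// Single evaluation of the masked forward + loss components (used by R
// tests to cross-check the optimizer's objective).
// [[Rcpp::export]]
Rcpp::List explainer_eval_cpp(const arma::mat& X, const arma::mat& A,
                              const Rcpp::List& model_params,
                              const arma::mat& Mlog, const arma::vec& Flog,
                              int target_node, int target_class,
                              const arma::vec& theta, bool has_fc,
                              bool abs_diff, bool renormalize) {
  Model md = read_model(model_params, has_fc, abs_diff);
  Forward fw;
  forward_pass(X, A, md, Mlog, Flog, target_node, target_class,
               renormalize, fw);

  uvec sup = find(A > 0);
  vec sm = clamp(fw.sigM.elem(sup), 1e-12, 1.0 - 1e-12);
  vec sf = clamp(1.0 / (1.0 + exp(-Flog)), 1e-12, 1.0 - 1e-12);
  double ee = mean(-sm % log(sm) - (1.0 - sm) % log(1.0 - sm));
  double fe = mean(-sf % log(sf) - (1.0 - sf) % log(1.0 - sf));
  double total = fw.nll + theta(0) * ee + theta(1) * fe +
                 theta(2) * mean(sm) + theta(3) * mean(sf);
  return Rcpp::List::create(
      Rcpp::Named("total") = total, Rcpp::Named("pred_nll") = fw.nll,
      Rcpp::Named("edge_entropy") = theta(0) * ee,
      Rcpp::Named("feat_entropy") = theta(1) * fe,
      Rcpp::Named("edge_size") = theta(2) * mean(sm),
      Rcpp::Named("feat_size") = theta(3) * mean(sf),
      Rcpp::Named("prob") = Rcpp::NumericVector(fw.prob.begin(),
                                                fw.prob.end()));
}

// Optimize masks for one instance.  Mlog must be symmetric; Flog has one
// logit per feature column.  Returns sigmoid masks and the loss trace.
// [[Rcpp::export]]
Rcpp::List explain_instance_cpp(const arma::mat& X, const arma::mat& A,
                                const Rcpp::List& model_params,
                                arma::mat Mlog, arma::vec Flog,
                                int target_node, int target_class,
                                const arma::vec& theta, double lr,
                                int epochs, bool has_fc, bool abs_diff,
                                bool optimize_features, bool renormalize) {
  Model md = read_model(model_params, has_fc, abs_diff);
  const size_t K = md.W.size();
  const uword nv = X.n_rows;
  const uword f = X.n_cols;
  umat supmask = A > 0;
  uvec sup = find(supmask);
  const double nsup = (double)sup.n_elem;

  mat mM(nv, nv, fill::zeros), vM(nv, nv, fill::zeros);
  vec mF(f, fill::zeros), vF(f, fill::zeros);
  mat mask_accum(nv, nv, fill::zeros);  // time-averaged sigmoid mask
  const double b1a = 0.9, b2a = 0.999, epsa = 1e-8;
  std::vector<double> trace;
  trace.reserve(epochs);
  Forward fw;

  for (int ep = 1; ep <= epochs; ++ep) {
    forward_pass(X, A, md, Mlog, Flog, target_node, target_class,
                 renormalize, fw);
    mask_accum += fw.sigM;
    vec sigF = 1.0 / (1.0 + exp(-Flog));

    {
      vec sm = clamp(fw.sigM.elem(sup), 1e-12, 1.0 - 1e-12);
      vec sf = clamp(sigF, 1e-12, 1.0 - 1e-12);
      double ee = mean(-sm % log(sm) - (1.0 - sm) % log(1.0 - sm));
      double fe = mean(-sf % log(sf) - (1.0 - sf) % log(1.0 - sf));
      trace.push_back(fw.nll + theta(0) * ee + theta(1) * fe +
                      theta(2) * mean(sm) + theta(3) * mean(sf));
    }

    // ---- backward ----
    rowvec dz = fw.prob;
    dz(target_class) -= 1.0;

    mat dUk;
    if (!md.has_fc) {
      dUk.zeros(nv, fw.Upre[K - 1].n_cols);
      dUk.row(target_node) = dz;
    } else {
      rowvec df1 = dz * md.Wf2.t();
      rowvec duf1 = df1 % conv_to<rowvec>::from(fw.f1pre > 0);
      rowvec dv = duf1 * md.Wf1.t();
      const uword hK = fw.Upre[K - 1].n_cols;
      mat dHK(nv, hK);
      for (uword i = 0; i < nv; ++i)
        for (uword k = 0; k < hK; ++k) dHK(i, k) = dv(i * hK + k);
      dUk = dHK % conv_to<mat>::from(fw.Upre[K - 1] > 0);
    }

    mat dSuse(nv, nv, fill::zeros);
    mat dXs(nv, f, fill::zeros);
    for (size_t k = K; k-- > 0;) {
      dSuse += dUk * fw.M[k].t();
      mat dMk = fw.Suse.t() * dUk;
      if (k > 0) {
        mat dHprev = dMk * md.W[k].t();
        dUk = dHprev % conv_to<mat>::from(fw.Upre[k - 1] > 0);
      } else {
        dXs += dMk * md.W[0].t();
      }
    }

    mat dsigM_pred(nv, nv, fill::zeros);
    mat dS = dSuse;
    if (!renormalize) {
      dsigM_pred = dSuse % fw.S;
      dS = dSuse % fw.sigM;
    }

    // softmax-row backward: de_ij = (dS_ij - rho_i) / s_i
    vec rho = sum(dS % fw.S, 1);
    mat de = dS;
    de.each_col() -= rho;
    de.each_col() /= fw.srow;

    mat dEm = de % fw.EX;
    mat dEX = de % fw.Em;
    mat dU = dEX % fw.EX %
             conv_to<mat>::from((fw.U > 0) % (fw.U < 60.0));
    mat dGt(nv, md.P.n_cols, fill::zeros);
    for (uword k = 0; k < md.P.n_cols; ++k) {
      mat D = repmat(fw.Gt.col(k), 1, nv) - repmat(fw.Gt.col(k).t(), nv, 1);
      mat T = dU % (md.abs_diff ? sign(D) : mat(nv, nv, fill::ones));
      T *= md.a(k);
      dGt.col(k) = sum(T, 1) - sum(T, 0).t();
    }
    dXs += dGt * md.P.t();

    // edge-mask gradient: prediction path + regularizers on support
    mat dsigM = renormalize ? mat(dEm % A) : dsigM_pred;
    vec smc = clamp(fw.sigM.elem(sup), 1e-12, 1.0 - 1e-12);
    vec dreg = (theta(0) * log((1.0 - smc) / smc) + theta(2)) / nsup;
    for (uword t = 0; t < sup.n_elem; ++t) dsigM(sup(t)) += dreg(t);
    mat dMlog = dsigM % fw.sigM % (1.0 - fw.sigM);
    dMlog = 0.5 * (dMlog + dMlog.t());
    dMlog.elem(find(supmask == 0)).zeros();

    // feature-mask gradient
    vec sigFc = clamp(1.0 / (1.0 + exp(-Flog)), 1e-12, 1.0 - 1e-12);
    vec dsigF = sum(dXs % X, 0).t();
    dsigF += (theta(1) * log((1.0 - sigFc) / sigFc) + theta(3)) / (double)f;
    vec dFlog = dsigF % sigFc % (1.0 - sigFc);

    // ---- Adam ----
    double c1 = 1.0 - std::pow(b1a, ep), c2 = 1.0 - std::pow(b2a, ep);
    mM = b1a * mM + (1.0 - b1a) * dMlog;
    vM = b2a * vM + (1.0 - b2a) * square(dMlog);
    Mlog -= lr * (mM / c1) / (sqrt(vM / c2) + epsa);
    if (optimize_features) {
      mF = b1a * mF + (1.0 - b1a) * dFlog;
      vF = b2a * vF + (1.0 - b2a) * square(dFlog);
      Flog -= lr * (mF / c1) / (sqrt(vF / c2) + epsa);
    }
  }

  forward_pass(X, A, md, Mlog, Flog, target_node, target_class,
               renormalize, fw);
  return Rcpp::List::create(
      Rcpp::Named("edge_mask") = sigm(Mlog),
      Rcpp::Named("edge_mask_avg") = mask_accum / (double)epochs,
      Rcpp::Named("edge_logits") = Mlog,
      Rcpp::Named("feat_mask") = 1.0 / (1.0 + exp(-Flog)),
      Rcpp::Named("feat_logits") = Flog,
      Rcpp::Named("loss_trace") = trace,
      Rcpp::Named("final_prob") = Rcpp::NumericVector(fw.prob.begin(),
                                                      fw.prob.end()));
}
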