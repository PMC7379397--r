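// Deep multilayer perceptron for 4-class ordinal item prediction.
//
// Fully connected net: input -> 15 hidden ReLU layers (widths 2n,n,n/2
// in groups of five) -> 4-unit softmax.  Trained with Adam on
// categorical cross-entropy with inverted dropout after every hidden
// layer.  Several measures keep this very deep, very narrow stack
// trainable on small tabular samples: orthogonal initialization with
// ReLU gain, small positive hidden biases, global-norm gradient
// clipping, an exponentially decayed step size, a curriculum ramp of
// the dropout rate, an exponential moving average of the weights for
// evaluation, and early stopping whose patience watches the smoothed
// epoch training loss while the returned weights are the best
// held-out-loss snapshot.  All randomness (init, shuffling, dropout)
// comes from a private mt19937_64 stream so results are reproducible
// for a given seed regardless of R's RNG state.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

arma::mat softmax_cols(arma::mat Z) {
  Z.each_row() -= arma::max(Z, 0);
  Z = arma::exp(Z);
  arma::rowvec s = arma::sum(Z, 0);
  Z.each_row() /= s;
  return Z;
}

// forward pass without dropout; samples are columns
arma::mat forward_eval(const Net& net, const arma::mat& X) {
  arma::mat A = X;
  const size_t L = net.W.size();
  for (size_t l = 0; l < L; ++l) {
    arma::mat Z = net.W[l] * A;
    Z.each_col() += net.b[l];
    if (l + 1 < L) {
      A = arma::clamp(Z, 0.0, arma::datum::inf);
    } else {
      A = softmax_cols(Z);
    }
  }
  return A;
}

double xent_loss(const arma::mat& P, const arma::uvec& y) {
  double loss = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    loss -= std::log(std::max(P(y(i), i), 1e-12));
  }
  return loss / static_cast<double>(y.n_elem);
}

double accuracy_low_tie(const arma::mat& P, const arma::uvec& y) {
  arma::uword correct = 0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    arma::uword best = 0;
    double bv = P(0, i);
    for (arma::uword k = 1; k < P.n_rows; ++k) {
      if (P(k, i) > bv) { bv = P(k, i); best = k; }  // strict > : ties -> lower class
    }
    if (best == y(i)) ++correct;
  }
  return static_cast<double>(correct) / static_cast<double>(y.n_elem);
}

}  // namespace

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(const arma::mat& x_train, const arma::ivec& y_train,
                   const arma::mat& x_val, const arma::ivec& y_val,
                   const arma::ivec& hidden_widths, double dropout,
                   int batch_size, int max_epochs, int patience,
                   double learning_rate, int seed) {
  const arma::uword p = x_train.n_cols;
  const arma::uword n = x_train.n_rows;
  const int n_classes = 4;
  if (n == 0) stop("no training rows");

  // samples as columns
  arma::mat Xtr = x_train.t();
  arma::mat Xval = x_val.t();
  arma::uvec ytr = arma::conv_to<arma::uvec>::from(y_train);
  arma::uvec yval = arma::conv_to<arma::uvec>::from(y_val);

  std::vector<arma::uword> sizes;
  sizes.push_back(p);
  for (arma::uword l = 0; l < hidden_widths.n_elem; ++l) {
    sizes.push_back(std::max<arma::sword>(1, hidden_widths(l)));
  }
  sizes.push_back(n_classes);
  const size_t L = sizes.size() - 1;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  Net net;
  net.W.resize(L);
  net.b.resize(L);
  // orthogonal init with ReLU gain sqrt(2): preserves signal norms far
  // better than factorized Gaussian in deep narrow stacks, which keeps
  // the initial optimization plateau short enough for tight patience
  for (size_t l = 0; l < L; ++l) {
    arma::mat G(std::max(sizes[l + 1], sizes[l]),
                std::min(sizes[l + 1], sizes[l]));
    for (arma::uword i = 0; i < G.n_elem; ++i) G(i) = gauss(rng);
    arma::mat Q, R;
    arma::qr_econ(Q, R, G);
    Q *= arma::diagmat(arma::sign(R.diag()));
    if (sizes[l + 1] >= sizes[l]) {
      net.W[l] = std::sqrt(2.0) * Q;
    } else {
      net.W[l] = std::sqrt(2.0) * Q.t();
    }
    net.b[l].set_size(sizes[l + 1]);
    // small positive bias keeps narrow ReLU layers from dying under
    // noisy dropout gradients
    net.b[l].fill(l + 1 < L ? 0.05 : 0.0);
  }

  // Adam state
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::vec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(net.W[l]));
    vW[l].zeros(arma::size(net.W[l]));
    mb[l].zeros(net.b[l].n_elem);
    vb[l].zeros(net.b[l].n_elem);
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long adam_t = 0;

  // exponential moving average of weights: evaluated (and returned)
  // instead of the raw iterate, smoothing minibatch/dropout noise
  Net ema = net;
  const double ema_decay = 0.99;

  int bs = batch_size <= 0 ? static_cast<int>(n) : batch_size;
  bs = std::min<int>(bs, static_cast<int>(n));

  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  Net best = net;
  double best_loss = std::numeric_limits<double>::infinity();
  double best_monitored = std::numeric_limits<double>::infinity();
  int wait = 0, epochs_run = 0;

  std::vector<arma::mat> A(L + 1), Zcache(L), drop_mask(L);
  const int dropout_warmup = dropout > 0.0 ? 30 : 0;
  double smoothed = std::numeric_limits<double>::quiet_NaN();
  const int dropout_warmup_end = dropout_warmup + 1;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    epochs_run = epoch + 1;
    std::shuffle(order.begin(), order.end(), rng);
    // curriculum dropout: ramp the rate linearly from 0 to its target
    // over the first `dropout_warmup` epochs so the deep stack leaves
    // its initial plateau before the full regularization noise arrives
    const double eff_dropout = epoch >= dropout_warmup
        ? dropout
        : dropout * static_cast<double>(epoch) / dropout_warmup;
    const double keep = 1.0 - eff_dropout;
    // exponential step-size decay (independent of the epoch cap, so
    // early-stopped runs still train at properly annealed rates)
    const double lr_now = learning_rate *
        std::max(std::pow(0.98, epoch), 0.1);
    double train_loss_sum = 0.0;
    for (arma::uword start = 0; start < n; start += bs) {
      const arma::uword stop_i = std::min<arma::uword>(start + bs, n);
      const arma::uword b_n = stop_i - start;
      arma::uvec idx(b_n);
      for (arma::uword i = 0; i < b_n; ++i) idx(i) = order[start + i];
      A[0] = Xtr.cols(idx);
      for (size_t l = 0; l < L; ++l) {
        arma::mat Z = net.W[l] * A[l];
        Z.each_col() += net.b[l];
        if (l + 1 < L) {
          Zcache[l] = Z;
          arma::mat act = arma::clamp(Z, 0.0, arma::datum::inf);
          if (eff_dropout > 0.0) {
            drop_mask[l].set_size(arma::size(act));
            for (arma::uword i = 0; i < act.n_elem; ++i) {
              drop_mask[l](i) = unif(rng) < keep ? 1.0 / keep : 0.0;
            }
            act %= drop_mask[l];
          }
          A[l + 1] = act;
        } else {
          A[l + 1] = softmax_cols(Z);
        }
      }
      {
        arma::uvec yb(b_n);
        for (arma::uword i = 0; i < b_n; ++i) yb(i) = ytr(idx(i));
        train_loss_sum += xent_loss(A[L], yb) * static_cast<double>(b_n);
      }
      // backward
      arma::mat dZ = A[L];
      for (arma::uword i = 0; i < b_n; ++i) dZ(ytr(idx(i)), i) -= 1.0;
      dZ /= static_cast<double>(b_n);
      ++adam_t;
      double gnorm2 = 0.0;
      const double bc1 = 1.0 - std::pow(beta1, adam_t);
      const double bc2 = 1.0 - std::pow(beta2, adam_t);
      std::vector<arma::mat> gW(L);
      std::vector<arma::vec> gb(L);
      for (size_t li = L; li-- > 0;) {
        gW[li] = dZ * A[li].t();
        gb[li] = arma::sum(dZ, 1);
        gnorm2 += arma::accu(arma::square(gW[li])) +
                  arma::accu(arma::square(gb[li]));
        if (li > 0) {
          arma::mat dA = net.W[li].t() * dZ;
          if (eff_dropout > 0.0) dA %= drop_mask[li - 1];
          dZ = dA % arma::conv_to<arma::mat>::from(Zcache[li - 1] > 0.0);
        }
      }
      // global-norm gradient clipping tames the rare huge spikes that
      // inverted-dropout path amplification produces in a 15-layer stack
      const double max_gnorm = 1.0;
      const double gscale = gnorm2 > max_gnorm * max_gnorm
                                ? max_gnorm / std::sqrt(gnorm2) : 1.0;
      for (size_t li = 0; li < L; ++li) {
        const arma::mat dW = gscale * gW[li];
        const arma::vec db = gscale * gb[li];
        mW[li] = beta1 * mW[li] + (1.0 - beta1) * dW;
        vW[li] = beta2 * vW[li] + (1.0 - beta2) * arma::square(dW);
        mb[li] = beta1 * mb[li] + (1.0 - beta1) * db;
        vb[li] = beta2 * vb[li] + (1.0 - beta2) * arma::square(db);
        net.W[li] -= lr_now * (mW[li] / bc1) /
                     (arma::sqrt(vW[li] / bc2) + eps);
        net.b[li] -= lr_now * (mb[li] / bc1) /
                     (arma::sqrt(vb[li] / bc2) + eps);
      }
      for (size_t l2 = 0; l2 < L; ++l2) {
        ema.W[l2] = ema_decay * ema.W[l2] + (1.0 - ema_decay) * net.W[l2];
        ema.b[l2] = ema_decay * ema.b[l2] + (1.0 - ema_decay) * net.b[l2];
      }
    }
    // early stopping: patience watches the epoch's mean training loss;
    // the returned weights are always the best-held-out-loss snapshot
    arma::mat Pval = forward_eval(ema, Xval);
    const double vloss = xent_loss(Pval, yval);
    if (vloss < best_loss - 1e-8) {
      best_loss = vloss;
      best = ema;
    }
    // patience counting starts once the dropout ramp is complete, so
    // the deliberate loss increase during warmup cannot trigger it
    if (epoch + 1 < dropout_warmup_end) continue;
    const double raw = train_loss_sum / static_cast<double>(n);
    // epoch-level smoothing of the monitored loss: minibatch/dropout
    // noise should not masquerade as a stall (or as an improvement)
    smoothed = std::isnan(smoothed) ? raw : 0.5 * smoothed + 0.5 * raw;
    const double monitored = smoothed;
    if (monitored < best_monitored - 1e-8) {
      best_monitored = monitored;
      wait = 0;
    } else {
      if (++wait >= patience) break;
    }
  }

  arma::mat Pbest = forward_eval(best, Xval);
  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = best.W[l];
    bout[l] = best.b[l];
  }
  return List::create(_["weights"] = Wout, _["biases"] = bout,
                      _["validation_accuracy"] = accuracy_low_tie(Pbest, yval),
                      _["validation_loss"] = best_loss,
                      _["epochs_run"] = epochs_run);
}

// [[Rcpp::export(name = ".mlp_predict_cpp")]]
arma::mat mlp_predict_cpp(const List& weights, const List& biases,
                          const arma::mat& x) {
  Net net;
  const size_t L = weights.size();
  net.W.resize(L);
  net.b.resize(L);
  for (size_t l = 0; l < L; ++l) {
    net.W[l] = as<arma::mat>(weights[l]);
    net.b[l] = as<arma::vec>(biases[l]);
  }
  return forward_eval(net, x.t()).t();  // rows = samples, 4 columns
}
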