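#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Layout conventions (all arrays are R column-major):
//   spike tensor  : dim (T, C, H, W)          -> t + T*(c + C*(h + H*w))
//   conv kernel   : dim (k, k, Cin, Cout)     -> dm + k*(dn + k*(ci + Cin*co))
//   conv map      : dim (oh, ow, Cout)        -> r + oh*(c + ow*co)
//   pooled feature: dim (ph, pw, Cout), packed per branch into one flat vector
//   fc weights    : dim (n_out, n_in)

struct BranchSpec {
  int k, cin, cout, oh, ow, ph, pw;
  double *kernel;      // owned by R
  double *tau;         // per neuron, dim (oh, ow, cout)
};

struct FcSpec {
  int n_out, n_in;
  double *W;
  double *tau;
};

struct NetSpec {
  std::vector<BranchSpec> br;
  std::vector<FcSpec> fc;
  int T, C, H, W, n_feat, n_class;
  double dt, Rm, vth, vreset;
  int pool; // 0 = max (binary OR), 1 = avg (graded current)
};

// options for one learning presentation
struct LearnOpts {
  bool learn = false;
  int eps = 0;
  double eta = 0.0;
  bool gated = true;      // teaching signal only at output-error steps
  bool train_conv = true;
  double clip_lo = -1.0, clip_hi = 1.0;
  int label = 0;
};

static NetSpec parse_net(List branches, List fc, List params) {
  NetSpec s;
  s.T = as<int>(params["timesteps"]);
  s.C = as<int>(params["in_channels"]);
  s.H = as<int>(params["in_height"]);
  s.W = as<int>(params["in_width"]);
  s.dt = as<double>(params["dt"]);
  s.Rm = as<double>(params["resistance"]);
  s.vth = as<double>(params["threshold"]);
  s.vreset = as<double>(params["reset"]);
  s.pool = as<int>(params["pool"]);
  s.n_feat = 0;
  for (int b = 0; b < branches.size(); ++b) {
    List bl = branches[b];
    NumericVector kern = bl["kernel"];
    NumericVector tau = bl["tau"];
    IntegerVector kd = kern.attr("dim");
    BranchSpec bs;
    bs.k = kd[0]; bs.cin = kd[2]; bs.cout = kd[3];
    if (bs.cin != s.C) stop("kernel input channels do not match input tensor");
    bs.oh = s.H - bs.k + 1; bs.ow = s.W - bs.k + 1;
    if (bs.oh < 1 || bs.ow < 1) stop("kernel larger than input");
    bs.ph = bs.oh / 2; bs.pw = bs.ow / 2;
    bs.kernel = kern.begin();
    bs.tau = tau.begin();
    if ((int)tau.size() != bs.oh * bs.ow * bs.cout) stop("branch tau size mismatch");
    s.n_feat += bs.ph * bs.pw * bs.cout;
    s.br.push_back(bs);
  }
  int n_in = s.n_feat;
  for (int l = 0; l < fc.size(); ++l) {
    List fl = fc[l];
    NumericMatrix W = fl["W"];
    NumericVector tau = fl["tau"];
    FcSpec fs;
    fs.n_out = W.nrow(); fs.n_in = W.ncol();
    if (fs.n_in != n_in) stop("fc layer input size mismatch");
    if ((int)tau.size() != fs.n_out) stop("fc tau size mismatch");
    fs.W = &W(0, 0);
    fs.tau = tau.begin();
    s.fc.push_back(fs);
    n_in = fs.n_out;
  }
  s.n_class = n_in;
  return s;
}

static inline double clipd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// rolling sum of the last (eps+1) presynaptic vectors, the
// sum_{f = t-eps..t} s_h(f) window of the plasticity rule
struct RollingCount {
  int eps = 0, head = 0, n = 0;
  std::vector<double> buf;   // (eps+1) stacked vectors
  std::vector<double> sum;
  void init(int eps_, int n_) {
    eps = eps_; n = n_; head = 0;
    buf.assign((size_t)(eps + 1) * n, 0.0);
    sum.assign(n, 0.0);
  }
  void push(const double *x) {
    double *slot = buf.data() + (size_t)head * n;
    for (int i = 0; i < n; ++i) {
      sum[i] += x[i] - slot[i];
      slot[i] = x[i];
    }
    head = (head + 1) % (eps + 1);
  }
};

// One sample presentation; when opts.learn, accumulates per-timestep weight
// deltas (applied with clipping at the end of the sample) for the output
// layer, hidden fc layers and - optionally - the conv kernels.
static void run_sample(NetSpec &s, const double *S,
                       std::vector<double> &counts,
                       int *out_spikes, /* T x M or NULL */
                       const LearnOpts &opts) {
  const int T = s.T, C = s.C, H = s.H, W = s.W;
  const int L = (int)s.fc.size();
  std::vector<std::vector<double>> Vb(s.br.size());
  for (size_t b = 0; b < s.br.size(); ++b)
    Vb[b].assign(s.br[b].oh * s.br[b].ow * s.br[b].cout, s.vreset);
  std::vector<std::vector<double>> Vf(L);
  for (int l = 0; l < L; ++l) Vf[l].assign(s.fc[l].n_out, s.vreset);
  std::fill(counts.begin(), counts.end(), 0.0);

  std::vector<double> feat(s.n_feat);
  std::vector<double> x, xn, cur;
  std::vector<std::vector<int>> spk(s.br.size());
  for (size_t b = 0; b < s.br.size(); ++b) spk[b].resize(Vb[b].size());

  // learning state
  RollingCount rc_in;
  std::vector<RollingCount> rc_fc(L);
  std::vector<std::vector<double>> dW(L);
  std::vector<std::vector<double>> dK(s.br.size());
  std::vector<std::vector<double>> alpha(L + 1);
  if (opts.learn) {
    rc_in.init(opts.eps, C * H * W);
    for (int l = 0; l < L; ++l) {
      rc_fc[l].init(opts.eps, s.fc[l].n_in);
      dW[l].assign((size_t)s.fc[l].n_out * s.fc[l].n_in, 0.0);
      alpha[l].resize(s.fc[l].n_in);
    }
    alpha[L].resize(s.n_class);
    for (size_t b = 0; b < s.br.size(); ++b)
      dK[b].assign((size_t)s.br[b].k * s.br[b].k * s.br[b].cin * s.br[b].cout, 0.0);
  }
  std::vector<double> input_t;
  if (opts.learn) input_t.resize((size_t)C * H * W);

  for (int t = 0; t < T; ++t) {
    // --- parallel conv branches ---
    int off = 0;
    for (size_t b = 0; b < s.br.size(); ++b) {
      const BranchSpec &bs = s.br[b];
      int n = bs.oh * bs.ow * bs.cout;
      cur.assign(n, 0.0);
      // scatter-add from active input pixels (spikes are sparse binary)
      for (int w = 0; w < W; ++w) for (int h = 0; h < H; ++h) for (int ci = 0; ci < C; ++ci) {
        double sp = S[t + (size_t)T * (ci + C * (h + (size_t)H * w))];
        if (sp == 0.0) continue;
        if (opts.learn && b == 0) input_t[ci + C * (h + (size_t)H * w)] = sp;
        int r0 = std::max(0, h - bs.k + 1), r1 = std::min(bs.oh - 1, h);
        int c0 = std::max(0, w - bs.k + 1), c1 = std::min(bs.ow - 1, w);
        for (int co = 0; co < bs.cout; ++co) {
          const double *K = bs.kernel + (size_t)bs.k * bs.k * (ci + (size_t)bs.cin * co);
          double *I = cur.data() + (size_t)bs.oh * bs.ow * co;
          for (int c = c0; c <= c1; ++c) {
            int dn = w - c;
            for (int r = r0; r <= r1; ++r)
              I[r + bs.oh * c] += K[(h - r) + bs.k * dn];
          }
        }
      }
      // LIF update + spikes
      std::vector<double> &V = Vb[b];
      std::vector<int> &sp2 = spk[b];
      for (int i = 0; i < n; ++i) {
        V[i] += (s.dt / bs.tau[i]) * (-V[i] + s.Rm * cur[i]);
        if (V[i] >= s.vth) { sp2[i] = 1; V[i] = s.vreset; } else sp2[i] = 0;
      }
      // 2x2 pool on the binary spike map
      for (int co = 0; co < bs.cout; ++co) {
        const int *Mp = sp2.data() + (size_t)bs.oh * bs.ow * co;
        for (int pc = 0; pc < bs.pw; ++pc) for (int pr = 0; pr < bs.ph; ++pr) {
          int a = Mp[2 * pr + bs.oh * (2 * pc)], b2 = Mp[2 * pr + 1 + bs.oh * (2 * pc)];
          int c = Mp[2 * pr + bs.oh * (2 * pc + 1)], d = Mp[2 * pr + 1 + bs.oh * (2 * pc + 1)];
          double v;
          if (s.pool == 0) v = (a | b2 | c | d) ? 1.0 : 0.0;
          else v = (a + b2 + c + d) / 4.0;
          feat[off + pr + bs.ph * (pc + (size_t)bs.pw * co)] = v;
        }
      }
      off += bs.ph * bs.pw * bs.cout;
    }

    if (opts.learn) {
      rc_in.push(input_t.data());
      std::fill(input_t.begin(), input_t.end(), 0.0);
    }

    // --- fully connected chain ---
    x = feat;
    for (int l = 0; l < L; ++l) {
      const FcSpec &fs = s.fc[l];
      if (opts.learn) rc_fc[l].push(x.data());
      cur.assign(fs.n_out, 0.0);
      for (int h = 0; h < fs.n_in; ++h) {
        double xh = x[h];
        if (xh == 0.0) continue;
        const double *Wc = fs.W + (size_t)fs.n_out * h;
        for (int i = 0; i < fs.n_out; ++i) cur[i] += Wc[i] * xh;
      }
      xn.assign(fs.n_out, 0.0);
      std::vector<double> &V = Vf[l];
      for (int i = 0; i < fs.n_out; ++i) {
        V[i] += (s.dt / fs.tau[i]) * (-V[i] + s.Rm * cur[i]);
        if (V[i] >= s.vth) { xn[i] = 1.0; V[i] = s.vreset; }
      }
      x = xn;
    }
    for (int i = 0; i < s.n_class; ++i) {
      counts[i] += x[i];
      if (out_spikes) out_spikes[t + (size_t)T * i] = (int)x[i];
    }

    // --- per-timestep plasticity ---
    if (opts.learn) {
      bool any = false;
      std::vector<double> &aout = alpha[L];
      for (int i = 0; i < s.n_class; ++i) {
        double d = (i == opts.label) ? 1.0 : 0.0;
        double a = (d == 1.0) ? 1.0 : -1.0;
        if (opts.gated && x[i] == d) a = 0.0;   // output already correct here
        aout[i] = a;
        if (a != 0.0) any = true;
      }
      if (any) {
        // backpropagate sign-thresholded signals with pre-sample weights
        for (int l = L - 1; l >= 0; --l) {
          const FcSpec &fs = s.fc[l];
          std::vector<double> &ain = alpha[l];
          const std::vector<double> &adown = alpha[l + 1];
          for (int h = 0; h < fs.n_in; ++h) {
            double acc = 0.0;
            const double *Wc = fs.W + (size_t)fs.n_out * h;
            for (int i = 0; i < fs.n_out; ++i)
              if (adown[i] != 0.0) acc += Wc[i] * adown[i];
            ain[h] = (double)((acc > 0) - (acc < 0));
          }
        }
        // fc weight deltas: eta * alpha_i(t) * windowed presyn count
        for (int l = 0; l < L; ++l) {
          const FcSpec &fs = s.fc[l];
          const std::vector<double> &adown = alpha[l + 1];
          const std::vector<double> &ws = rc_fc[l].sum;
          double *D = dW[l].data();
          for (int h = 0; h < fs.n_in; ++h) {
            double wsh = ws[h];
            if (wsh == 0.0) continue;
            double *Dc = D + (size_t)fs.n_out * h;
            for (int i = 0; i < fs.n_out; ++i)
              if (adown[i] != 0.0) Dc[i] += opts.eta * adown[i] * wsh;
          }
        }
        // conv kernel deltas: each conv neuron inherits its pooled unit's
        // signal; correlate with windowed input counts, averaged over the
        // positions sharing the kernel
        if (opts.train_conv) {
          int foff = 0;
          const std::vector<double> &afeat = alpha[0];
          for (size_t b = 0; b < s.br.size(); ++b) {
            const BranchSpec &bs = s.br[b];
            double npos = (double)(2 * bs.ph) * (2 * bs.pw);
            for (int co = 0; co < bs.cout; ++co) {
              for (int pc = 0; pc < bs.pw; ++pc) for (int pr = 0; pr < bs.ph; ++pr) {
                double a = afeat[foff + pr + bs.ph * (pc + (size_t)bs.pw * co)];
                if (a == 0.0) continue;
                double scale = opts.eta * a / npos;
                for (int dr = 0; dr < 2; ++dr) for (int dc = 0; dc < 2; ++dc) {
                  int r = 2 * pr + dr, c = 2 * pc + dc;   // conv position
                  for (int ci = 0; ci < bs.cin; ++ci) {
                    double *Kd = dK[b].data() + (size_t)bs.k * bs.k * (ci + (size_t)bs.cin * co);
                    for (int dn = 0; dn < bs.k; ++dn) for (int dm = 0; dm < bs.k; ++dm) {
                      double w = rc_in.sum[ci + C * ((r + dm) + (size_t)H * (c + dn))];
                      if (w != 0.0) Kd[dm + bs.k * dn] += scale * w;
                    }
                  }
                }
              }
            }
            foff += bs.ph * bs.pw * bs.cout;
          }
        }
      }
    }
  }

  // apply accumulated deltas with clipping (per-sample online update)
  if (opts.learn) {
    for (int l = 0; l < L; ++l) {
      FcSpec &fs = s.fc[l];
      const double *D = dW[l].data();
      size_t nw = (size_t)fs.n_out * fs.n_in;
      for (size_t i = 0; i < nw; ++i)
        if (D[i] != 0.0)
          fs.W[i] = clipd(fs.W[i] + D[i], opts.clip_lo, opts.clip_hi);
    }
    if (opts.train_conv) {
      for (size_t b = 0; b < s.br.size(); ++b) {
        BranchSpec &bs = s.br[b];
        const double *D = dK[b].data();
        size_t nk = (size_t)bs.k * bs.k * bs.cin * bs.cout;
        for (size_t i = 0; i < nk; ++i)
          if (D[i] != 0.0)
            bs.kernel[i] = clipd(bs.kernel[i] + D[i], opts.clip_lo, opts.clip_hi);
      }
    }
  }
}

// [[Rcpp::export]]
List snn_forward_cpp(List branches, List fc, NumericVector input, List params) {
  NetSpec s = parse_net(branches, fc, params);
  IntegerVector d = input.attr("dim");
  if (d.size() != 4 || d[0] != s.T || d[1] != s.C || d[2] != s.H || d[3] != s.W)
    stop("input tensor shape does not match network configuration");
  std::vector<double> counts(s.n_class);
  IntegerMatrix out_spikes(s.T, s.n_class);
  LearnOpts opts;
  run_sample(s, input.begin(), counts, &out_spikes(0, 0), opts);
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["output_spikes"] = out_spikes);
}

// [[Rcpp::export]]
List snn_train_cpp(List branches, List fc, List inputs, IntegerVector labels,
                   IntegerMatrix order, List params) {
  NetSpec s = parse_net(branches, fc, params);
  const int epochs = order.nrow(), n = order.ncol();
  LearnOpts opts;
  opts.learn = true;
  opts.eps = as<int>(params["window"]);
  opts.eta = as<double>(params["learning_rate"]);
  opts.gated = as<bool>(params["gated"]);
  opts.train_conv = as<bool>(params["train_conv"]);
  opts.clip_lo = as<double>(params["clip_lo"]);
  opts.clip_hi = as<double>(params["clip_hi"]);
  const double rate = as<double>(params["tau_rate"]);
  const double tau_lo = as<double>(params["tau_lo"]);
  const double tau_hi = as<double>(params["tau_hi"]);
  const int tau_mode = as<int>(params["tau_mode"]); // 0 anchored, 1 recurrent

  // tau arrays are updated in place (the R caller passes deep copies)
  std::vector<double *> tau_init_br(s.br.size());
  for (size_t b = 0; b < s.br.size(); ++b) {
    List bl = branches[b];
    NumericVector ti = bl["tau_init"];
    tau_init_br[b] = ti.begin();
  }
  std::vector<double *> tau_init_fc(s.fc.size());
  for (size_t l = 0; l < s.fc.size(); ++l) {
    List fl = fc[l];
    NumericVector ti = fl["tau_init"];
    tau_init_fc[l] = ti.begin();
  }

  const int M = s.n_class;
  std::vector<double> counts(M);
  NumericVector Evec(epochs), accvec(epochs), tau_mean(epochs), tau_sd(epochs);
  NumericMatrix tau_trace(epochs, M);

  for (int ep = 0; ep < epochs; ++ep) {
    double Esum = 0.0; int ncorrect = 0;
    for (int j = 0; j < n; ++j) {
      int idx = order(ep, j);
      NumericVector input = inputs[idx];
      opts.label = labels[idx];
      run_sample(s, input.begin(), counts, nullptr, opts);
      double e = 0.0; int best = 0;
      for (int i = 0; i < M; ++i) {
        double d = (i == opts.label) ? 1.0 : 0.0;
        double o = counts[i] / s.T;
        e += (d - o) * (d - o);
        if (counts[i] > counts[best]) best = i;
      }
      Esum += e;
      if (best == opts.label) ++ncorrect;
    }

    double E = Esum / n;
    Evec[ep] = E;
    accvec[ep] = (double)ncorrect / n;

    // per-neuron time-constant evolution at epoch end
    double tsum = 0.0, tsq = 0.0; long tn = 0;
    for (size_t b = 0; b < s.br.size(); ++b) {
      BranchSpec &bs = s.br[b];
      int nn = bs.oh * bs.ow * bs.cout;
      for (int i = 0; i < nn; ++i) {
        double base = (tau_mode == 0) ? tau_init_br[b][i] : bs.tau[i];
        bs.tau[i] = clipd(base * std::exp(rate * E), tau_lo, tau_hi);
        tsum += bs.tau[i]; tsq += bs.tau[i] * bs.tau[i]; ++tn;
      }
    }
    for (size_t l = 0; l < s.fc.size(); ++l) {
      FcSpec &fs = s.fc[l];
      for (int i = 0; i < fs.n_out; ++i) {
        double base = (tau_mode == 0) ? tau_init_fc[l][i] : fs.tau[i];
        fs.tau[i] = clipd(base * std::exp(rate * E), tau_lo, tau_hi);
        tsum += fs.tau[i]; tsq += fs.tau[i] * fs.tau[i]; ++tn;
      }
    }
    for (int i = 0; i < M; ++i) tau_trace(ep, i) = s.fc.back().tau[i];
    tau_mean[ep] = tsum / tn;
    double var = (tn > 1) ? (tsq - tsum * tsum / tn) / (tn - 1) : 0.0;
    tau_sd[ep] = std::sqrt(std::max(0.0, var));
  }

  return List::create(_["branches"] = branches, _["fc"] = fc,
                      _["E"] = Evec, _["acc"] = accvec,
                      _["tau_trace"] = tau_trace,
                      _["tau_mean"] = tau_mean, _["tau_sd"] = tau_sd);
}
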