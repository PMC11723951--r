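#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Lattice reaction-diffusion-binding stepper for nuclear FRAP simulation.
//
// Two fluorescent fields live on a 2D pixel grid: F (free, diffusing at
// D_free) and B (bound). The bound field may itself diffuse slowly with
// no-flux coupling confined to the site region (site_region mask): this
// models site-to-site transfer ("hopping"/facilitated dissociation) of
// bound molecules along the immobile chromatin scaffold without full
// release into the free pool. Each step is Lie-split:
//   1. explicit 5-point diffusion of F (coupling restricted to the nucleus
//      mask) and of B (coupling restricted to the site region); the
//      symmetric stencils conserve mass up to floating-point roundoff;
//   2. exact per-pixel relaxation of the linear exchange
//         dF/dt = -kon*F + koff*B,  dB/dt = +kon*F - koff*B
//      using the closed-form solution, so stiff binding rates do not
//      constrain dt (only the diffusion CFL bound does).
//
// kon here is the pseudo-first-order on-rate kon_per_site * free-site
// occupancy, precomputed per pixel by the caller.

// [[Rcpp::export]]
List rd_run(NumericMatrix F, NumericMatrix B,
            LogicalMatrix nucleus, NumericMatrix kon,
            double koff, double alpha, double alpha_b,
            LogicalMatrix site_region, double dt,
            int n_steps, int record_every,
            IntegerMatrix roi_labels, int n_rois,
            bool store_frames) {
  const int nr = F.nrow(), nc = F.ncol();
  NumericMatrix Fw(clone(F)), Bw(clone(B));
  NumericMatrix Fn(nr, nc);

  const int n_frames = (record_every > 0) ? (n_steps / record_every) : 0;
  NumericMatrix roi_means(n_frames, n_rois);
  NumericVector frame_steps(n_frames);
  List frames(store_frames ? n_frames : 0);

  // per-pixel reaction propagator terms (time-invariant)
  NumericMatrix efac(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double lam = kon(i, j) + koff;
      efac(i, j) = (lam > 0) ? std::exp(-lam * dt) : 1.0;
    }

  int frame = 0;
  for (int s = 1; s <= n_steps; ++s) {
    // diffusion (free field only); neighbours outside the nucleus do not
    // exchange, which implements the reflecting nuclear envelope
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!nucleus(i, j)) { Fn(i, j) = Fw(i, j); continue; }
        double f = Fw(i, j), acc = 0.0;
        if (i > 0      && nucleus(i - 1, j)) acc += Fw(i - 1, j) - f;
        if (i < nr - 1 && nucleus(i + 1, j)) acc += Fw(i + 1, j) - f;
        if (j > 0      && nucleus(i, j - 1)) acc += Fw(i, j - 1) - f;
        if (j < nc - 1 && nucleus(i, j + 1)) acc += Fw(i, j + 1) - f;
        Fn(i, j) = f + alpha * acc;
      }
    }
    // bound-field hopping along the site lattice
    if (alpha_b > 0) {
      NumericMatrix Bn(nr, nc);
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!site_region(i, j)) { Bn(i, j) = Bw(i, j); continue; }
          double b = Bw(i, j), acc = 0.0;
          if (i > 0      && site_region(i - 1, j)) acc += Bw(i - 1, j) - b;
          if (i < nr - 1 && site_region(i + 1, j)) acc += Bw(i + 1, j) - b;
          if (j > 0      && site_region(i, j - 1)) acc += Bw(i, j - 1) - b;
          if (j < nc - 1 && site_region(i, j + 1)) acc += Bw(i, j + 1) - b;
          Bn(i, j) = b + alpha_b * acc;
        }
      }
      Bw = Bn;
    }
    // exact two-state exchange
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!nucleus(i, j)) { Fw(i, j) = Fn(i, j); continue; }
        double lam = kon(i, j) + koff;
        if (lam <= 0) { Fw(i, j) = Fn(i, j); continue; }
        double tot = Fn(i, j) + Bw(i, j);
        double feq = tot * koff / lam;
        double f = feq + (Fn(i, j) - feq) * efac(i, j);
        Fw(i, j) = f;
        Bw(i, j) = tot - f;
      }
    }
    if (record_every > 0 && s % record_every == 0) {
      std::vector<double> sums(n_rois, 0.0);
      std::vector<int> counts(n_rois, 0);
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          int lab = roi_labels(i, j);
          if (lab >= 1 && lab <= n_rois) {
            sums[lab - 1] += Fw(i, j) + Bw(i, j);
            counts[lab - 1] += 1;
          }
        }
      for (int r = 0; r < n_rois; ++r)
        roi_means(frame, r) = counts[r] ? sums[r] / counts[r] : NA_REAL;
      frame_steps[frame] = s;
      if (store_frames) {
        NumericMatrix snap(nr, nc);
        for (int j = 0; j < nc; ++j)
          for (int i = 0; i < nr; ++i)
            snap(i, j) = Fw(i, j) + Bw(i, j);
        frames[frame] = snap;
      }
      ++frame;
    }
  }

  return List::create(_["F"] = Fw, _["B"] = Bw,
                      _["roi_means"] = roi_means,
                      _["frame_steps"] = frame_steps,
                      _["frames"] = frames);
}

// Total fluorescence (F + B) over the grid; used for conservation checks.
// [[Rcpp::export]]
double rd_total(NumericMatrix F, NumericMatrix B) {
  double s = 0.0;
  for (int j = 0; j < F.ncol(); ++j)
    for (int i = 0; i < F.nrow(); ++i)
      s += F(i, j) + B(i, j);
  return s;
}

// 4-connected component labelling of a logical mask (flood fill).
// Returns an integer matrix with components numbered from 1; background 0.
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j0 = 0; j0 < nc; ++j0)
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      ++next;
      lab(i0, j0) = next;
      q.push(std::make_pair(i0, j0));
      while (!q.empty()) {
        int i = q.front().first, j = q.front().second;
        q.pop();
        if (i > 0      && mask(i - 1, j) && !lab(i - 1, j)) { lab(i - 1, j) = next; q.push(std::make_pair(i - 1, j)); }
        if (i < nr - 1 && mask(i + 1, j) && !lab(i + 1, j)) { lab(i + 1, j) = next; q.push(std::make_pair(i + 1, j)); }
        if (j > 0      && mask(i, j - 1) && !lab(i, j - 1)) { lab(i, j - 1) = next; q.push(std::make_pair(i, j - 1)); }
        if (j < nc - 1 && mask(i, j + 1) && !lab(i, j + 1)) { lab(i, j + 1) = next; q.push(std::make_pair(i, j + 1)); }
      }
    }
  return lab;
}
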