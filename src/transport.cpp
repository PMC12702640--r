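// Meridian-plane polarized-light Monte Carlo core for a laterally unbounded
// slab.  Stokes vectors are carried in the meridian frame of the current
// propagation direction (parallel axis in the plane spanned by k and the
// depth axis); each scattering event rotates into the scattering plane,
// applies the single-sphere Mueller matrix, and rotates back into the new
// meridian frame.  Reference frames are maintained as explicit orthonormal
// triads (v, w, k) with v x w = k, which fixes every rotation sign without
// spherical-trigonometry case analysis.
//
// Scattering tables are the complex Mie amplitudes S1, S2 per particle
// radius, linearly interpolated in theta; the Mueller elements are formed
// from the interpolated amplitudes so the per-event matrix is exactly pure
// (Jones-derivable) and per-photon polarization is preserved to roundoff.
//
// All randomness comes from R's generator (unif_rand), so set.seed() in R
// makes runs bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator*(double s, V3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline V3 normalize(V3 a) {
  double n = std::sqrt(dot(a, a));
  return {a.x / n, a.y / n, a.z / n};
}

struct Stokes {
  double I, Q, U, V;
};

// Rotate the Stokes reference frame by gamma about the propagation
// direction, given cos(gamma) and sin(gamma) (new parallel axis =
// cos(g) * v + sin(g) * w).
inline void rotate_frame(Stokes &s, double cg, double sg) {
  double c2 = cg * cg - sg * sg;
  double s2 = 2.0 * sg * cg;
  double q = s.Q * c2 + s.U * s2;
  double u = -s.Q * s2 + s.U * c2;
  s.Q = q;
  s.U = u;
}

// Meridian frame of direction k (|k_z| < 1): w along k x zhat, v = w x k,
// so v lies in the plane of k and the depth axis and v x w = k.
inline bool meridian_frame(const V3 &k, V3 &v, V3 &w) {
  double st2 = k.x * k.x + k.y * k.y;
  if (st2 < 1e-24) return false;
  double inv = 1.0 / std::sqrt(st2);
  w = {k.y * inv, -k.x * inv, 0.0};
  v = cross(w, k);
  return true;
}

struct AmpTables {
  int n_theta, K;
  const double *re1, *im1, *re2, *im2;  // n_theta x K, column-major
  double dtheta_inv;                    // (n_theta - 1) / pi

  // interpolate amplitudes and form Mueller elements at (theta, radius k)
  void elements(double theta, int k, double &s11, double &s12, double &s33,
                double &s34) const {
    double u = theta * dtheta_inv;
    int i0 = (int)u;
    if (i0 >= n_theta - 1) i0 = n_theta - 2;
    double f = u - i0;
    const double *c1r = re1 + (size_t)k * n_theta;
    const double *c1i = im1 + (size_t)k * n_theta;
    const double *c2r = re2 + (size_t)k * n_theta;
    const double *c2i = im2 + (size_t)k * n_theta;
    double a1r = c1r[i0] + f * (c1r[i0 + 1] - c1r[i0]);
    double a1i = c1i[i0] + f * (c1i[i0 + 1] - c1i[i0]);
    double a2r = c2r[i0] + f * (c2r[i0 + 1] - c2r[i0]);
    double a2i = c2i[i0] + f * (c2i[i0 + 1] - c2i[i0]);
    double m1 = a1r * a1r + a1i * a1i;
    double m2 = a2r * a2r + a2i * a2i;
    s11 = 0.5 * (m2 + m1);
    s12 = 0.5 * (m2 - m1);
    // S2* S1
    s33 = a2r * a1r + a2i * a1i;
    s34 = a2r * a1i - a2i * a1r;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_run_transport")]]
List cpp_run_transport(int n_photons, int n_batches, double mu_a, double mu_s,
                       double thickness, double incidence_deg,
                       NumericVector launch_stokes, NumericVector cum_w,
                       NumericMatrix re1, NumericMatrix im1, NumericMatrix re2,
                       NumericMatrix im2, NumericVector max_s11,
                       NumericVector max_as12, double collect_radius,
                       double accept_cos, int event_cap, int max_tries,
                       bool weighted_mode, double roulette_threshold,
                       double roulette_p, bool fresnel, double n_rel,
                       bool record) {
  if (n_photons < 1) stop("n_photons must be >= 1");
  double mu_t = mu_a + mu_s;
  if (mu_t <= 0) stop("mu_a + mu_s must be positive (infinite step otherwise)");
  const int K = cum_w.size();
  AmpTables tab{(int)re1.nrow(), K, REAL(re1), REAL(im1),
                REAL(re2), REAL(im2), (re1.nrow() - 1) / M_PI};

  const double alpha = incidence_deg * M_PI / 180.0;
  // entry refraction (Fresnel mode bends the beam; matched mode does not)
  double sin_in = std::sin(alpha), cos_in = std::cos(alpha);
  double sin_t = fresnel ? sin_in / n_rel : sin_in;
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  // entry transmission amplitudes (p = in-plane = launch parallel axis)
  double tp_in = 1.0, ts_in = 1.0, T_in = 1.0;
  if (fresnel) {
    tp_in = 2.0 * cos_in / (n_rel * cos_in + cos_t);
    ts_in = 2.0 * cos_in / (cos_in + n_rel * cos_t);
    double Tp = n_rel * cos_t / cos_in * tp_in * tp_in;
    double Ts = n_rel * cos_t / cos_in * ts_in * ts_in;
    double Ip = 0.5 * (launch_stokes[0] + launch_stokes[1]);
    double Is = 0.5 * (launch_stokes[0] - launch_stokes[1]);
    T_in = (Tp * Ip + Ts * Is) / (Ip + Is);
  }

  NumericMatrix batch_stokes(n_batches, 4);
  IntegerVector batch_detected(n_batches);
  NumericVector batch_weight(n_batches);
  double tally_detected = 0, tally_undetected = 0, tally_transmitted = 0,
         tally_absorbed = 0, tally_cap = 0, tally_roulette = 0,
         tally_specular = 0;
  double det_weight_sum = 0.0;  // independent accumulator for bookkeeping
  std::vector<double> rec;

  for (int ip = 0; ip < n_photons; ++ip) {
    int batch = (int)((double)ip * n_batches / n_photons);
    // --- launch: pencil beam at the origin ---
    V3 pos{0.0, 0.0, 0.0};
    V3 k{sin_t, 0.0, cos_t};
    V3 v, w;
    if (!meridian_frame(k, v, w)) {  // normal incidence: pole convention
      v = {-1.0, 0.0, 0.0};
      w = {0.0, -1.0, 0.0};
    }
    Stokes S{launch_stokes[0], launch_stokes[1], launch_stokes[2],
             launch_stokes[3]};
    double weight = 1.0;
    int ne = 0;
    if (fresnel) {
      if (unif_rand() >= T_in) {
        tally_specular += 1.0;
        continue;
      }
      // transmission Jones on (p, s) = (parallel, perp) in the launch frame
      double Ip = 0.5 * (S.I + S.Q) * tp_in * tp_in;
      double Is = 0.5 * (S.I - S.Q) * ts_in * ts_in;
      double u = S.U * tp_in * ts_in, vv = S.V * tp_in * ts_in;
      double Inew = Ip + Is;
      double sc = weight / Inew;
      S = {weight, (Ip - Is) * sc, u * sc, vv * sc};
    }

    int status = 0;  // 0 alive, then one of the terminal codes
    while (true) {
      // --- free path (average mu_s of the medium, not per-size) ---
      double s_len = -std::log(unif_rand()) / mu_t;
      // --- boundary crossings along this step ---
      bool terminated = false;
      while (true) {
        double z_end = pos.z + s_len * k.z;
        if (k.z < 0.0 && z_end < 0.0) {
          double t = -pos.z / k.z;
          V3 exitp = pos + t * k;
          if (fresnel) {
            double ci = -k.z;  // cos of internal incidence on top surface
            double sr = n_rel * std::sqrt(1.0 - ci * ci);
            if (sr >= 1.0) {  // total internal reflection
              pos = exitp;
              s_len -= t;
              k.z = -k.z;
              if (!meridian_frame(k, v, w)) { /* keep frame */ }
              continue;
            }
            double ct = std::sqrt(1.0 - sr * sr);
            // frame (v,w) is the meridian frame = plane of incidence basis
            double rp = (ct - n_rel * ci) / (ct + n_rel * ci);
            double rs = (ci - n_rel * ct) / (ci + n_rel * ct);
            double Ip = 0.5 * (S.I + S.Q), Is = 0.5 * (S.I - S.Q);
            double Rphot = (rp * rp * Ip + rs * rs * Is) / S.I;
            if (unif_rand() < Rphot) {  // internal reflection
              pos = exitp;
              s_len -= t;
              double Ipr = Ip * rp * rp, Isr = Is * rs * rs;
              double ur = S.U * rp * rs, vr = S.V * rp * rs;
              double sc = weight / (Ipr + Isr);
              S = {weight, (Ipr - Isr) * sc, ur * sc, vr * sc};
              k.z = -k.z;
              meridian_frame(k, v, w);
              continue;
            }
            // refract out (dense -> rare, relative index n_rel)
            double tpp = 2.0 * n_rel * ci / (ci + n_rel * ct);
            double tss = 2.0 * n_rel * ci / (n_rel * ci + ct);
            double Ipt = Ip * tpp * tpp, Ist = Is * tss * tss;
            double ut = S.U * tpp * tss, vt = S.V * tpp * tss;
            double sc = weight / (Ipt + Ist);
            S = {weight, (Ipt - Ist) * sc, ut * sc, vt * sc};
            double stf = sr / std::sqrt(k.x * k.x + k.y * k.y);
            k = normalize(V3{k.x * stf, k.y * stf, -ct});
            meridian_frame(k, v, w);
          }
          // --- exited the top surface: detection test ---
          double r_exit = std::sqrt(exitp.x * exitp.x + exitp.y * exitp.y);
          double upcos = -k.z;
          if (r_exit <= collect_radius && upcos >= accept_cos) {
            // rotate Stokes into the detector frame (parallel axis = lab x
            // projected transverse to k)
            V3 a{1.0 - k.x * k.x, -k.x * k.y, -k.x * k.z};
            double an = std::sqrt(dot(a, a));
            if (an > 1e-12) {
              a = (1.0 / an) * a;
              double cg = dot(a, v), sg = dot(a, w);
              rotate_frame(S, cg, sg);
            }
            batch_stokes(batch, 0) += S.I;
            batch_stokes(batch, 1) += S.Q;
            batch_stokes(batch, 2) += S.U;
            batch_stokes(batch, 3) += S.V;
            batch_detected[batch] += 1;
            batch_weight[batch] += weight;
            det_weight_sum += weight;
            tally_detected += 1.0;
            if (record) {
              double row[11] = {(double)ne, weight, S.I,    S.Q,
                                S.U,        S.V,    exitp.x, exitp.y,
                                k.x,        k.y,    k.z};
              rec.insert(rec.end(), row, row + 11);
            }
          } else {
            tally_undetected += 1.0;
          }
          status = 1;
          terminated = true;
          break;
        } else if (k.z > 0.0 && z_end > thickness) {
          if (fresnel) {
            double ci = k.z;
            double sr = n_rel * std::sqrt(1.0 - ci * ci);
            if (sr < 1.0) {
              double ct = std::sqrt(1.0 - sr * sr);
              double rp = (ct - n_rel * ci) / (ct + n_rel * ci);
              double rs = (ci - n_rel * ct) / (ci + n_rel * ct);
              double Ip = 0.5 * (S.I + S.Q), Is = 0.5 * (S.I - S.Q);
              double Rphot = (rp * rp * Ip + rs * rs * Is) / S.I;
              if (unif_rand() >= Rphot) {  // transmitted out the bottom
                tally_transmitted += 1.0;
                status = 2;
                terminated = true;
                break;
              }
              double t = (thickness - pos.z) / k.z;
              pos = pos + t * k;
              s_len -= t;
              double Ipr = Ip * rp * rp, Isr = Is * rs * rs;
              double ur = S.U * rp * rs, vr = S.V * rp * rs;
              double sc = weight / (Ipr + Isr);
              S = {weight, (Ipr - Isr) * sc, ur * sc, vr * sc};
              k.z = -k.z;
              meridian_frame(k, v, w);
              continue;
            }
            // TIR at bottom
            double t = (thickness - pos.z) / k.z;
            pos = pos + t * k;
            s_len -= t;
            k.z = -k.z;
            continue;
          }
          tally_transmitted += 1.0;
          status = 2;
          terminated = true;
          break;
        }
        pos = pos + s_len * k;
        break;
      }
      if (terminated) break;

      // --- interaction ---
      if (weighted_mode) {
        double alb = mu_s / mu_t;
        weight *= alb;
        S.I *= alb;
        S.Q *= alb;
        S.U *= alb;
        S.V *= alb;
        if (weight < roulette_threshold) {
          if (unif_rand() < roulette_p) {
            double f = 1.0 / roulette_p;
            weight *= f;
            S.I *= f;
            S.Q *= f;
            S.U *= f;
            S.V *= f;
          } else {
            tally_roulette += 1.0;
            status = 5;
            break;
          }
        }
      } else if (mu_a > 0.0 && unif_rand() < mu_a / mu_t) {
        tally_absorbed += 1.0;
        status = 3;
        break;
      }

      // --- draw the particle size for this event ---
      double uu = unif_rand();
      int lo = 0, hi = K - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum_w[mid] < uu)
          lo = mid + 1;
        else
          hi = mid;
      }
      int kr = lo;

      // --- rejection-sample (theta, psi) from P(theta, psi) sin(theta) ---
      // |s12| <= s11 <= max-knot s11 everywhere (|S_i(t)|^2 is convex along
      // an interpolation segment), so this envelope provably dominates.
      double lin = std::sqrt(S.Q * S.Q + S.U * S.U);
      double Pmax = 1.01 * max_s11[kr] * (S.I + lin);
      (void)max_as12;
      double theta = 0.0, psi = 0.0, s11 = 0, s12 = 0, s33 = 0, s34 = 0;
      int tries = 0;
      while (true) {
        if (++tries > max_tries)
          stop("rejection sampler exceeded max_tries: envelope broken");
        double mu_c = 1.0 - 2.0 * unif_rand();
        theta = std::acos(mu_c);
        psi = 2.0 * M_PI * unif_rand();
        tab.elements(theta, kr, s11, s12, s33, s34);
        double c2p = std::cos(2.0 * psi), s2p = std::sin(2.0 * psi);
        double P = s11 * S.I + s12 * (S.Q * c2p + S.U * s2p);
        if (unif_rand() * Pmax < P) break;
      }

      // --- meridian-plane Stokes and direction update ---
      double cp = std::cos(psi), sp = std::sin(psi);
      rotate_frame(S, cp, sp);  // into the scattering plane
      V3 vs{cp * v.x + sp * w.x, cp * v.y + sp * w.y, cp * v.z + sp * w.z};
      V3 ws{-sp * v.x + cp * w.x, -sp * v.y + cp * w.y, -sp * v.z + cp * w.z};
      double ct = std::cos(theta), st = std::sin(theta);
      V3 k_new = normalize(V3{ct * k.x + st * vs.x, ct * k.y + st * vs.y,
                              ct * k.z + st * vs.z});
      V3 e_par{ct * vs.x - st * k.x, ct * vs.y - st * k.y, ct * vs.z - st * k.z};
      // Mueller action of the sphere (pure, from interpolated amplitudes)
      double In = s11 * S.I + s12 * S.Q;
      double Qn = s12 * S.I + s11 * S.Q;
      double Un = s33 * S.U + s34 * S.V;
      double Vn = -s34 * S.U + s33 * S.V;
      double sc = weight / In;
      S = {weight, Qn * sc, Un * sc, Vn * sc};
      // back into the meridian frame of the new direction
      V3 v_new, w_new;
      if (meridian_frame(k_new, v_new, w_new)) {
        double cg = dot(v_new, e_par), sg = dot(v_new, ws);
        rotate_frame(S, cg, sg);
        v = v_new;
        w = w_new;
      } else {  // propagation along the depth axis: carry the rotated frame
        v = e_par;
        w = ws;
      }
      k = k_new;

      ne += 1;
      if (ne > event_cap) {
        tally_cap += 1.0;
        status = 4;
        break;
      }
    }
    (void)status;
  }

  NumericVector det(4);
  for (int b = 0; b < n_batches; ++b)
    for (int j = 0; j < 4; ++j) det[j] += batch_stokes(b, j);

  List out = List::create(
      _["detector_stokes"] = det, _["batch_stokes"] = batch_stokes,
      _["batch_detected"] = batch_detected, _["batch_weight"] = batch_weight,
      _["detected_weight_sum"] = det_weight_sum,
      _["tallies"] = NumericVector::create(
          _["reflected_detected"] = tally_detected,
          _["reflected_undetected"] = tally_undetected,
          _["transmitted"] = tally_transmitted,
          _["absorbed"] = tally_absorbed,
          _["event_cap_killed"] = tally_cap,
          _["roulette_killed"] = tally_roulette,
          _["specular_reflected"] = tally_specular));
  if (record) {
    int nrow = rec.size() / 11;
    NumericMatrix recm(11, nrow);
    std::copy(rec.begin(), rec.end(), recm.begin());
    out["detections"] = recm;
  }
  return out;
}

// Single-draw rejection sampler over a tabulated element set; used by the
// R-level sample_scattering_angles() so unit tests exercise the same
// envelope logic as the core.
// [[Rcpp::export(name = ".cpp_sample_angles")]]
NumericVector cpp_sample_angles(NumericVector stokes, NumericVector theta_grid,
                                NumericVector s11, NumericVector s12,
                                int max_tries) {
  int n = theta_grid.size();
  double m11 = 0, m12 = 0;
  for (int i = 0; i < n; ++i) {
    if (s11[i] > m11) m11 = s11[i];
    if (std::fabs(s12[i]) > m12) m12 = std::fabs(s12[i]);
  }
  double lin = std::sqrt(stokes[1] * stokes[1] + stokes[2] * stokes[2]);
  double Pmax = 1.01 * (stokes[0] * m11 + lin * m12);
  double span = theta_grid[n - 1] - theta_grid[0];
  int tries = 0;
  while (true) {
    if (++tries > max_tries)
      stop("rejection sampler exceeded max_tries: envelope broken");
    double mu_c = 1.0 - 2.0 * unif_rand();
    double theta = std::acos(mu_c);
    double psi = 2.0 * M_PI * unif_rand();
    double u = (theta - theta_grid[0]) / span * (n - 1);
    int i0 = (int)u;
    if (i0 >= n - 1) i0 = n - 2;
    double f = u - i0;
    double e11 = s11[i0] + f * (s11[i0 + 1] - s11[i0]);
    double e12 = s12[i0] + f * (s12[i0 + 1] - s12[i0]);
    double P = e11 * stokes[0] +
               e12 * (stokes[1] * std::cos(2 * psi) + stokes[2] * std::sin(2 * psi));
    if (unif_rand() * Pmax < P)
      return NumericVector::create(theta, psi);
  }
}
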