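// Scale-invariant interest points (DoG pyramid + 128-d gradient descriptors),
// brute-force ratio matching, and a robust homography sampler.
//
// The detector follows the classic difference-of-Gaussians construction:
// incremental Gaussian pyramid, 3x3x3 extrema with quadratic sub-pixel
// refinement, contrast and edge-response rejection, orientation histograms
// and 4x4x8 gradient descriptors. Pixel reads outside the image are clamped
// (replicate border) so interest points close to the panel border can still
// be described; duplicated-content analysis benefits from near-border
// matches that a conservative border margin would discard.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct FImage {
  int w, h;
  std::vector<float> px; // row-major: px[y * w + x]
  FImage(int w_ = 0, int h_ = 0) : w(w_), h(h_), px((size_t)w_ * h_, 0.f) {}
  inline float at(int x, int y) const {
    if (x < 0) x = 0; else if (x >= w) x = w - 1;
    if (y < 0) y = 0; else if (y >= h) y = h - 1;
    return px[(size_t)y * w + x];
  }
  inline float atu(int x, int y) const { return px[(size_t)y * w + x]; }
};

// separable Gaussian blur, replicate border
FImage gaussianBlur(const FImage& src, double sigma) {
  if (sigma <= 0.01) return src;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<float> k(2 * radius + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -radius; i <= radius; ++i) { k[i + radius] = (float)std::exp(-(double)i * i / s2); sum += k[i + radius]; }
  for (auto& v : k) v = (float)(v / sum);
  FImage tmp(src.w, src.h), dst(src.w, src.h);
  for (int y = 0; y < src.h; ++y)
    for (int x = 0; x < src.w; ++x) {
      float acc = 0.f;
      for (int i = -radius; i <= radius; ++i) acc += k[i + radius] * src.at(x + i, y);
      tmp.px[(size_t)y * src.w + x] = acc;
    }
  for (int y = 0; y < src.h; ++y)
    for (int x = 0; x < src.w; ++x) {
      float acc = 0.f;
      for (int i = -radius; i <= radius; ++i) acc += k[i + radius] * tmp.at(x, y + i);
      dst.px[(size_t)y * src.w + x] = acc;
    }
  return dst;
}

FImage resizeBilinear(const FImage& src, int nw, int nh) {
  FImage dst(nw, nh);
  double sx = (double)src.w / nw, sy = (double)src.h / nh;
  for (int y = 0; y < nh; ++y) {
    double fy = (y + 0.5) * sy - 0.5;
    int y0 = (int)std::floor(fy); double wy = fy - y0;
    for (int x = 0; x < nw; ++x) {
      double fx = (x + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx); double wx = fx - x0;
      double v = (1 - wy) * ((1 - wx) * src.at(x0, y0) + wx * src.at(x0 + 1, y0)) +
                 wy * ((1 - wx) * src.at(x0, y0 + 1) + wx * src.at(x0 + 1, y0 + 1));
      dst.px[(size_t)y * nw + x] = (float)v;
    }
  }
  return dst;
}

FImage downsample2(const FImage& src) {
  FImage dst(std::max(1, src.w / 2), std::max(1, src.h / 2));
  for (int y = 0; y < dst.h; ++y)
    for (int x = 0; x < dst.w; ++x)
      dst.px[(size_t)y * dst.w + x] = src.at(2 * x, 2 * y);
  return dst;
}

struct KeyPt {
  double x, y;        // original image coordinates (0-based pixel centers)
  double size;        // sigma relative to the original image
  double angle;       // degrees in [0, 360)
  double response;
  int octave, layer;
  double ox, oy, scl; // position and scale within the octave image
};

const int N_LAYERS = 3;
const double SIGMA0 = 1.6;
const double INIT_SIGMA = 0.5;
const double CONTRAST_THR = 0.04;
const double EDGE_THR = 10.0;
const int DETECT_BORDER = 2;
const int MAX_INTERP_STEPS = 5;

// orientation histogram around (x, y); returns max value
double calcOrientationHist(const FImage& img, int x, int y, int radius,
                           double sigma, double* hist, int n) {
  double expf_scale = -1.0 / (2.0 * sigma * sigma);
  std::vector<double> temphist(n + 4, 0.0);
  for (int i = -radius; i <= radius; ++i) {
    for (int j = -radius; j <= radius; ++j) {
      double dx = img.at(x + j + 1, y + i) - img.at(x + j - 1, y + i);
      double dy = img.at(x + j, y + i - 1) - img.at(x + j, y + i + 1);
      double mag = std::sqrt(dx * dx + dy * dy);
      double ang = std::atan2(dy, dx); // radians
      double w = std::exp((i * i + j * j) * expf_scale);
      int bin = (int)std::lround(ang * n / (2.0 * M_PI));
      if (bin >= n) bin -= n;
      if (bin < 0) bin += n;
      temphist[bin + 2] += w * mag;
    }
  }
  // circular smoothing [1 4 6 4 1]/16
  temphist[0] = temphist[n];     temphist[1] = temphist[n + 1];
  temphist[n + 2] = temphist[2]; temphist[n + 3] = temphist[3];
  double maxval = 0.0;
  for (int i = 0; i < n; ++i) {
    hist[i] = (temphist[i] + temphist[i + 4]) * (1.0 / 16) +
              (temphist[i + 1] + temphist[i + 3]) * (4.0 / 16) +
              temphist[i + 2] * (6.0 / 16);
    maxval = std::max(maxval, hist[i]);
  }
  return maxval;
}

bool adjustLocalExtrema(const std::vector<FImage>& dog, KeyPt& kpt,
                        int octv, int& layer, int& r, int& c) {
  const double deriv_scale = 0.5, second_deriv_scale = 1.0, cross_deriv_scale = 0.25;
  double xi = 0, xr = 0, xc = 0, contr = 0;
  int i = 0;
  const int w = dog[0].w, h = dog[0].h;
  for (; i < MAX_INTERP_STEPS; ++i) {
    const FImage& img = dog[layer];
    const FImage& prv = dog[layer - 1];
    const FImage& nxt = dog[layer + 1];
    double dD[3] = { (img.at(c + 1, r) - img.at(c - 1, r)) * deriv_scale,
                     (img.at(c, r + 1) - img.at(c, r - 1)) * deriv_scale,
                     (nxt.at(c, r) - prv.at(c, r)) * deriv_scale };
    double v2 = img.at(c, r) * 2.0;
    double dxx = (img.at(c + 1, r) + img.at(c - 1, r) - v2) * second_deriv_scale;
    double dyy = (img.at(c, r + 1) + img.at(c, r - 1) - v2) * second_deriv_scale;
    double dss = (nxt.at(c, r) + prv.at(c, r) - v2) * second_deriv_scale;
    double dxy = (img.at(c + 1, r + 1) - img.at(c - 1, r + 1) -
                  img.at(c + 1, r - 1) + img.at(c - 1, r - 1)) * cross_deriv_scale;
    double dxs = (nxt.at(c + 1, r) - nxt.at(c - 1, r) -
                  prv.at(c + 1, r) + prv.at(c - 1, r)) * cross_deriv_scale;
    double dys = (nxt.at(c, r + 1) - nxt.at(c, r - 1) -
                  prv.at(c, r + 1) + prv.at(c, r - 1)) * cross_deriv_scale;
    // solve H * X = -dD (3x3, Cramer)
    double H[3][3] = { { dxx, dxy, dxs }, { dxy, dyy, dys }, { dxs, dys, dss } };
    double det = H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[2][1]) -
                 H[0][1] * (H[1][0] * H[2][2] - H[1][2] * H[2][0]) +
                 H[0][2] * (H[1][0] * H[2][1] - H[1][1] * H[2][0]);
    if (std::abs(det) < 1e-12) return false;
    double b[3] = { -dD[0], -dD[1], -dD[2] };
    auto det3 = [](double m[3][3]) {
      return m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
             m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
             m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
    };
    double M[3][3];
    double X[3];
    for (int k = 0; k < 3; ++k) {
      std::copy(&H[0][0], &H[0][0] + 9, &M[0][0]);
      M[0][k] = b[0]; M[1][k] = b[1]; M[2][k] = b[2];
      X[k] = det3(M) / det;
    }
    xc = X[0]; xr = X[1]; xi = X[2];
    if (std::abs(xc) < 0.5 && std::abs(xr) < 0.5 && std::abs(xi) < 0.5) {
      contr = img.at(c, r) + 0.5 * (dD[0] * xc + dD[1] * xr + dD[2] * xi);
      break;
    }
    c += (int)std::lround(xc);
    r += (int)std::lround(xr);
    layer += (int)std::lround(xi);
    if (layer < 1 || layer > N_LAYERS ||
        c < DETECT_BORDER || c >= w - DETECT_BORDER ||
        r < DETECT_BORDER || r >= h - DETECT_BORDER)
      return false;
  }
  if (i >= MAX_INTERP_STEPS) return false;
  if (std::abs(contr) * N_LAYERS < CONTRAST_THR) return false;
  // edge response
  {
    const FImage& img = dog[layer];
    double v2 = img.at(c, r) * 2.0;
    double dxx = img.at(c + 1, r) + img.at(c - 1, r) - v2;
    double dyy = img.at(c, r + 1) + img.at(c, r - 1) - v2;
    double dxy = (img.at(c + 1, r + 1) - img.at(c - 1, r + 1) -
                  img.at(c + 1, r - 1) + img.at(c - 1, r - 1)) * 0.25;
    double tr = dxx + dyy, det = dxx * dyy - dxy * dxy;
    if (det <= 0 || tr * tr * EDGE_THR >= (EDGE_THR + 1) * (EDGE_THR + 1) * det)
      return false;
  }
  kpt.ox = c + xc;
  kpt.oy = r + xr;
  kpt.scl = SIGMA0 * std::pow(2.0, (layer + xi) / N_LAYERS);
  kpt.response = std::abs(contr);
  kpt.layer = layer;
  return true;
}

void calcSIFTDescriptor(const FImage& img, double px, double py, double ori_deg,
                        double scl, float* dst) {
  const int d = 4, n = 8;
  double ori = ori_deg * M_PI / 180.0;
  double cos_t = std::cos(ori), sin_t = std::sin(ori);
  double bins_per_rad = n / (2.0 * M_PI);
  double exp_scale = -1.0 / (d * d * 0.5);
  double hist_width = 3.0 * scl;
  int radius = (int)std::lround(hist_width * M_SQRT2 * (d + 1) * 0.5);
  radius = std::min(radius, (int)std::sqrt((double)img.w * img.w + (double)img.h * img.h));
  cos_t /= hist_width; sin_t /= hist_width;
  std::vector<double> hist((d + 2) * (d + 2) * (n + 2), 0.0);
  int xi = (int)std::lround(px), yi = (int)std::lround(py);
  for (int i = -radius; i <= radius; ++i) {
    for (int j = -radius; j <= radius; ++j) {
      double c_rot = j * cos_t - i * sin_t;
      double r_rot = j * sin_t + i * cos_t;
      double rbin = r_rot + d / 2 - 0.5;
      double cbin = c_rot + d / 2 - 0.5;
      int y = yi + i, x = xi + j;
      if (rbin <= -1 || rbin >= d || cbin <= -1 || cbin >= d) continue;
      double dx = img.at(x + 1, y) - img.at(x - 1, y);
      double dy = img.at(x, y - 1) - img.at(x, y + 1);
      double mag = std::sqrt(dx * dx + dy * dy);
      double ang = std::atan2(dy, dx);
      double obin = (ang - ori) * bins_per_rad;
      double w = std::exp((c_rot * c_rot + r_rot * r_rot) * exp_scale);
      mag *= w;
      int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin), o0 = (int)std::floor(obin);
      rbin -= r0; cbin -= c0; obin -= o0;
      o0 = ((o0 % n) + n) % n;
      // trilinear interpolation into (d+2)x(d+2)x(n+2)
      double v_r1 = mag * rbin, v_r0 = mag - v_r1;
      double v_rc11 = v_r1 * cbin, v_rc10 = v_r1 - v_rc11;
      double v_rc01 = v_r0 * cbin, v_rc00 = v_r0 - v_rc01;
      double v_rco111 = v_rc11 * obin, v_rco110 = v_rc11 - v_rco111;
      double v_rco101 = v_rc10 * obin, v_rco100 = v_rc10 - v_rco101;
      double v_rco011 = v_rc01 * obin, v_rco010 = v_rc01 - v_rco011;
      double v_rco001 = v_rc00 * obin, v_rco000 = v_rc00 - v_rco001;
      int idx = ((r0 + 1) * (d + 2) + c0 + 1) * (n + 2) + o0;
      hist[idx] += v_rco000;
      hist[idx + 1] += v_rco001;
      hist[idx + (n + 2)] += v_rco010;
      hist[idx + (n + 3)] += v_rco011;
      hist[idx + (d + 2) * (n + 2)] += v_rco100;
      hist[idx + (d + 2) * (n + 2) + 1] += v_rco101;
      hist[idx + (d + 3) * (n + 2)] += v_rco110;
      hist[idx + (d + 3) * (n + 2) + 1] += v_rco111;
    }
  }
  // fold orientation wrap-around, copy to dst
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) {
      int idx = ((i + 1) * (d + 2) + (j + 1)) * (n + 2);
      hist[idx] += hist[idx + n];
      hist[idx + 1] += hist[idx + n + 1];
      for (int k = 0; k < n; ++k)
        dst[(i * d + j) * n + k] = (float)hist[idx + k];
    }
  // normalize, clip, renormalize
  int len = d * d * n;
  double nrm2 = 0;
  for (int k = 0; k < len; ++k) nrm2 += (double)dst[k] * dst[k];
  double thr = std::sqrt(nrm2) * 0.2;
  nrm2 = 0;
  for (int k = 0; k < len; ++k) {
    double v = std::min((double)dst[k], thr);
    dst[k] = (float)v;
    nrm2 += v * v;
  }
  nrm2 = 1.0 / std::max(std::sqrt(nrm2), 1e-12);
  for (int k = 0; k < len; ++k) dst[k] = (float)(dst[k] * nrm2);
}

} // namespace

// [[Rcpp::export(name = ".sift_detect")]]
List sift_detect(NumericMatrix gray, bool upscale = true, int max_keypoints = 2000) {
  const int h0 = gray.nrow(), w0 = gray.ncol();
  FImage base(w0, h0);
  for (int y = 0; y < h0; ++y)
    for (int x = 0; x < w0; ++x)
      base.px[(size_t)y * w0 + x] = (float)gray(y, x);

  int firstOctave = upscale ? -1 : 0;
  if (upscale) {
    base = resizeBilinear(base, w0 * 2, h0 * 2);
    double sig_diff = std::sqrt(std::max(SIGMA0 * SIGMA0 - 4.0 * INIT_SIGMA * INIT_SIGMA, 0.01));
    base = gaussianBlur(base, sig_diff);
  } else {
    double sig_diff = std::sqrt(std::max(SIGMA0 * SIGMA0 - INIT_SIGMA * INIT_SIGMA, 0.01));
    base = gaussianBlur(base, sig_diff);
  }
  int nOctaves = (int)std::floor(std::log2((double)std::min(base.w, base.h))) - 3;
  nOctaves = std::max(1, std::min(nOctaves, 8));

  // incremental blur sigmas
  std::vector<double> sig(N_LAYERS + 3);
  sig[0] = SIGMA0;
  double k = std::pow(2.0, 1.0 / N_LAYERS);
  for (int i = 1; i < N_LAYERS + 3; ++i) {
    double sig_prev = SIGMA0 * std::pow(k, i - 1);
    double sig_total = sig_prev * k;
    sig[i] = std::sqrt(sig_total * sig_total - sig_prev * sig_prev);
  }

  std::vector<KeyPt> keypoints;
  std::vector<std::vector<FImage>> gpyr(nOctaves);
  FImage cur = base;
  for (int o = 0; o < nOctaves; ++o) {
    std::vector<FImage>& gl = gpyr[o];
    gl.resize(N_LAYERS + 3);
    gl[0] = (o == 0) ? cur : downsample2(gpyr[o - 1][N_LAYERS]);
    for (int i = 1; i < N_LAYERS + 3; ++i) gl[i] = gaussianBlur(gl[i - 1], sig[i]);
    std::vector<FImage> dog(N_LAYERS + 2);
    for (int i = 0; i < N_LAYERS + 2; ++i) {
      dog[i] = FImage(gl[i].w, gl[i].h);
      for (size_t p = 0; p < dog[i].px.size(); ++p)
        dog[i].px[p] = gl[i + 1].px[p] - gl[i].px[p];
    }
    const int w = gl[0].w, hh = gl[0].h;
    double prethr = 0.5 * CONTRAST_THR / N_LAYERS;
    double scale_mult = std::pow(2.0, o + firstOctave);
    for (int layer = 1; layer <= N_LAYERS; ++layer) {
      const FImage& img = dog[layer];
      const FImage& prv = dog[layer - 1];
      const FImage& nxt = dog[layer + 1];
      for (int r = DETECT_BORDER; r < hh - DETECT_BORDER; ++r) {
        for (int c = DETECT_BORDER; c < w - DETECT_BORDER; ++c) {
          float val = img.atu(c, r);
          if (std::abs(val) <= prethr) continue;
          bool ismax = true, ismin = true;
          for (int dy = -1; dy <= 1 && (ismax || ismin); ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              float v1 = img.at(c + dx, r + dy);
              float v0 = prv.at(c + dx, r + dy);
              float v2 = nxt.at(c + dx, r + dy);
              if (val < v1 || val < v0 || val < v2) ismax = false;
              if (val > v1 || val > v0 || val > v2) ismin = false;
              if (!ismax && !ismin) break;
            }
          if (!ismax && !ismin) continue;
          KeyPt kpt;
          int lay = layer, rr = r, cc = c;
          if (!adjustLocalExtrema(dog, kpt, o, lay, rr, cc)) continue;
          kpt.octave = o;
          kpt.x = kpt.ox * scale_mult;
          kpt.y = kpt.oy * scale_mult;
          kpt.size = kpt.scl * scale_mult;
          // orientation(s)
          double hist[36];
          double sigma_ori = 1.5 * kpt.scl;
          int radius = (int)std::lround(3.0 * sigma_ori);
          double omax = calcOrientationHist(gpyr[o][kpt.layer],
                                            (int)std::lround(kpt.ox),
                                            (int)std::lround(kpt.oy),
                                            radius, sigma_ori, hist, 36);
          double mag_thr = omax * 0.8;
          for (int j = 0; j < 36; ++j) {
            int l = j > 0 ? j - 1 : 35;
            int r2 = j < 35 ? j + 1 : 0;
            if (hist[j] > hist[l] && hist[j] > hist[r2] && hist[j] >= mag_thr) {
              double bin = j + 0.5 * (hist[l] - hist[r2]) /
                           (hist[l] - 2 * hist[j] + hist[r2]);
              if (bin < 0) bin += 36; else if (bin >= 36) bin -= 36;
              KeyPt kp2 = kpt;
              kp2.angle = 360.0 - bin * 10.0;
              if (kp2.angle >= 360.0) kp2.angle -= 360.0;
              keypoints.push_back(kp2);
            }
          }
        }
      }
    }
  }

  // deterministic order: by response desc, then x, y, size, angle
  std::stable_sort(keypoints.begin(), keypoints.end(),
                   [](const KeyPt& a, const KeyPt& b) {
                     if (a.response != b.response) return a.response > b.response;
                     if (a.x != b.x) return a.x < b.x;
                     if (a.y != b.y) return a.y < b.y;
                     if (a.size != b.size) return a.size < b.size;
                     return a.angle < b.angle;
                   });
  if ((int)keypoints.size() > max_keypoints) keypoints.resize(max_keypoints);

  int n = keypoints.size();
  NumericMatrix pts(n, 4);        // x, y, size, angle (original image coords)
  NumericMatrix desc(n, 128);
  std::vector<float> buf(128);
  for (int idx = 0; idx < n; ++idx) {
    const KeyPt& kp = keypoints[idx];
    pts(idx, 0) = kp.x; pts(idx, 1) = kp.y;
    pts(idx, 2) = kp.size; pts(idx, 3) = kp.angle;
    double angle = 360.0 - kp.angle;
    if (angle >= 360.0) angle -= 360.0;
    calcSIFTDescriptor(gpyr[kp.octave][kp.layer], kp.ox, kp.oy, angle, kp.scl,
                       buf.data());
    for (int j = 0; j < 128; ++j) desc(idx, j) = buf[j];
  }
  colnames(pts) = CharacterVector::create("x", "y", "size", "angle");
  return List::create(_["points"] = pts, _["descriptors"] = desc);
}

// separable Gaussian blur of a numeric matrix (replicate border)
// [[Rcpp::export(name = ".gaussian_blur")]]
NumericMatrix gaussian_blur_mat(NumericMatrix m, double sigma) {
  FImage img(m.ncol(), m.nrow());
  for (int y = 0; y < img.h; ++y)
    for (int x = 0; x < img.w; ++x)
      img.px[(size_t)y * img.w + x] = (float)m(y, x);
  FImage out = gaussianBlur(img, sigma);
  NumericMatrix res(m.nrow(), m.ncol());
  for (int y = 0; y < out.h; ++y)
    for (int x = 0; x < out.w; ++x)
      res(y, x) = out.px[(size_t)y * out.w + x];
  return res;
}

// bilinear resize of a numeric matrix
// [[Rcpp::export(name = ".resize_bilinear")]]
NumericMatrix resize_bilinear_mat(NumericMatrix m, int width, int height) {
  FImage img(m.ncol(), m.nrow());
  for (int y = 0; y < img.h; ++y)
    for (int x = 0; x < img.w; ++x)
      img.px[(size_t)y * img.w + x] = (float)m(y, x);
  FImage out = resizeBilinear(img, width, height);
  NumericMatrix res(height, width);
  for (int y = 0; y < height; ++y)
    for (int x = 0; x < width; ++x)
      res(y, x) = out.px[(size_t)y * width + x];
  return res;
}

// ratio test over a precomputed squared-distance matrix (n1 x n2):
// returns 1-based index pairs where best < ratio^2 * second-best
// [[Rcpp::export(name = ".ratio_best")]]
IntegerMatrix ratio_best(NumericMatrix dist2, double ratio) {
  int n1 = dist2.nrow(), n2 = dist2.ncol();
  std::vector<int> mi, mj;
  if (n2 >= 2) {
    for (int i = 0; i < n1; ++i) {
      double best = 1e30, second = 1e30; int bj = -1;
      for (int j = 0; j < n2; ++j) {
        double s = dist2(i, j);
        if (s < best) { second = best; best = s; bj = j; }
        else if (s < second) second = s;
      }
      if (bj >= 0 && best < ratio * ratio * second) {
        mi.push_back(i + 1); mj.push_back(bj + 1);
      }
    }
  }
  IntegerMatrix out(mi.size(), 2);
  for (size_t i = 0; i < mi.size(); ++i) { out(i, 0) = mi[i]; out(i, 1) = mj[i]; }
  colnames(out) = CharacterVector::create("idx1", "idx2");
  return out;
}

namespace {
// xorshift64* PRNG: deterministic across platforms
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int uniform(int n) { return (int)(next() % (uint64_t)n); }
};

// homography from 4 point pairs via 8x8 Gaussian elimination (h33 = 1)
bool homography4(const double* px, const double* py, const double* qx,
                 const double* qy, const int* idx, double H[9]) {
  double A[8][9] = {{0}};
  for (int i = 0; i < 4; ++i) {
    double x = px[idx[i]], y = py[idx[i]], u = qx[idx[i]], v = qy[idx[i]];
    double* r1 = A[2 * i];
    double* r2 = A[2 * i + 1];
    r1[0] = x; r1[1] = y; r1[2] = 1; r1[6] = -u * x; r1[7] = -u * y; r1[8] = u;
    r2[3] = x; r2[4] = y; r2[5] = 1; r2[6] = -v * x; r2[7] = -v * y; r2[8] = v;
  }
  for (int col = 0; col < 8; ++col) {
    int piv = col;
    for (int r = col + 1; r < 8; ++r)
      if (std::abs(A[r][col]) > std::abs(A[piv][col])) piv = r;
    if (std::abs(A[piv][col]) < 1e-10) return false;
    if (piv != col) for (int cc = 0; cc < 9; ++cc) std::swap(A[piv][cc], A[col][cc]);
    for (int r = 0; r < 8; ++r) {
      if (r == col) continue;
      double f = A[r][col] / A[col][col];
      for (int cc = col; cc < 9; ++cc) A[r][cc] -= f * A[col][cc];
    }
  }
  for (int i = 0; i < 8; ++i) H[i] = A[i][8] / A[i][i];
  H[8] = 1.0;
  return true;
}

inline bool collinear3(double x1, double y1, double x2, double y2, double x3, double y3) {
  return std::abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) < 1e-6;
}
} // namespace

// Robust homography fit (RANSAC family, truncated-quadratic / MSAC scoring)
// on matched point pairs (P-side x/y, R-side x/y). Returns best H (row-major),
// 1-based inlier indices and the score. Deterministic given `seed`.
// [[Rcpp::export(name = ".ransac_homography")]]
List ransac_homography(NumericVector px, NumericVector py,
                       NumericVector qx, NumericVector qy,
                       double tol = 3.0, int max_iter = 2000,
                       double confidence = 0.995, double seed = 1.0) {
  int n = px.size();
  double tol2 = tol * tol;
  double bestScore = -1.0;
  double bestH[9] = {0};
  std::vector<int> bestInl;
  if (n >= 4) {
    XorShift rng((uint64_t)seed * 2654435761ULL + 88172645463325252ULL);
    int iters = max_iter;
    for (int it = 0; it < iters; ++it) {
      int idx[4];
      bool distinct = false;
      for (int tries = 0; tries < 50 && !distinct; ++tries) {
        for (int k = 0; k < 4; ++k) idx[k] = rng.uniform(n);
        distinct = idx[0] != idx[1] && idx[0] != idx[2] && idx[0] != idx[3] &&
                   idx[1] != idx[2] && idx[1] != idx[3] && idx[2] != idx[3];
        if (distinct) {
          // degenerate if any 3 sample points collinear (either side)
          for (int a = 0; a < 2 && distinct; ++a)
            for (int b = a + 1; b < 3 && distinct; ++b)
              for (int c = b + 1; c < 4; ++c) {
                if (collinear3(px[idx[a]], py[idx[a]], px[idx[b]], py[idx[b]],
                               px[idx[c]], py[idx[c]]) ||
                    collinear3(qx[idx[a]], qy[idx[a]], qx[idx[b]], qy[idx[b]],
                               qx[idx[c]], qy[idx[c]])) { distinct = false; break; }
              }
        }
      }
      if (!distinct) continue;
      double H[9];
      if (!homography4(px.begin(), py.begin(), qx.begin(), qy.begin(), idx, H))
        continue;
      double score = 0; int ninl = 0;
      for (int i = 0; i < n; ++i) {
        double w = H[6] * px[i] + H[7] * py[i] + H[8];
        if (std::abs(w) < 1e-12) { score += tol2; continue; }
        double u = (H[0] * px[i] + H[1] * py[i] + H[2]) / w;
        double v = (H[3] * px[i] + H[4] * py[i] + H[5]) / w;
        double e = (u - qx[i]) * (u - qx[i]) + (v - qy[i]) * (v - qy[i]);
        if (e < tol2) { score += tol2 - e; ++ninl; }
      }
      if (score > bestScore) {
        bestScore = score;
        std::copy(H, H + 9, bestH);
        bestInl.clear();
        for (int i = 0; i < n; ++i) {
          double w = bestH[6] * px[i] + bestH[7] * py[i] + bestH[8];
          if (std::abs(w) < 1e-12) continue;
          double u = (bestH[0] * px[i] + bestH[1] * py[i] + bestH[2]) / w;
          double v = (bestH[3] * px[i] + bestH[4] * py[i] + bestH[5]) / w;
          double e = (u - qx[i]) * (u - qx[i]) + (v - qy[i]) * (v - qy[i]);
          if (e < tol2) bestInl.push_back(i + 1);
        }
        // adaptive termination
        double w_in = (double)ninl / n;
        double p_out = 1.0 - std::pow(w_in, 4.0);
        p_out = std::min(std::max(p_out, 1e-12), 1.0 - 1e-12);
        int need = (int)std::ceil(std::log(1.0 - confidence) / std::log(p_out));
        if (need < iters) iters = std::max(need, it + 1);
      }
    }
  }
  NumericMatrix H(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) H(i, j) = bestH[3 * i + j];
  return List::create(_["H"] = H,
                      _["inliers"] = IntegerVector(bestInl.begin(), bestInl.end()),
                      _["score"] = bestScore,
                      _["found"] = bestScore > 0);
}
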