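// 3D texture-matrix accumulators. Grey levels are passed as a flattened
// integer array in column-major order with 0 marking voxels outside the
// mask and values 1..ng inside.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, const int* d) {
  return x + d[0] * (y + d[1] * z);
}

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dim, int ng,
                       IntegerMatrix offsets) {
  int d[3] = {dim[0], dim[1], dim[2]};
  int nd = offsets.nrow();
  NumericVector out(ng * ng * nd);
  for (int o = 0; o < nd; ++o) {
    int ox = offsets(o, 0), oy = offsets(o, 1), oz = offsets(o, 2);
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          int li = levels[idx3(x, y, z, d)];
          if (li == 0) continue;
          int x2 = x + ox, y2 = y + oy, z2 = z + oz;
          if (x2 < 0 || x2 >= d[0] || y2 < 0 || y2 >= d[1] ||
              z2 < 0 || z2 >= d[2]) continue;
          int lj = levels[idx3(x2, y2, z2, d)];
          if (lj == 0) continue;
          // symmetrized: count (i,j) and (j,i)
          out[(li - 1) + ng * (lj - 1) + ng * ng * o] += 1.0;
          out[(lj - 1) + ng * (li - 1) + ng * ng * o] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, nd);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng,
                        IntegerMatrix offsets) {
  int d[3] = {dim[0], dim[1], dim[2]};
  int nd = offsets.nrow();
  int maxrun = std::max(d[0], std::max(d[1], d[2]));
  NumericVector out(ng * maxrun * nd);
  for (int o = 0; o < nd; ++o) {
    int ox = offsets(o, 0), oy = offsets(o, 1), oz = offsets(o, 2);
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          int li = levels[idx3(x, y, z, d)];
          if (li == 0) continue;
          // start of a run: predecessor absent, out of grid, or different
          int xp = x - ox, yp = y - oy, zp = z - oz;
          bool start = true;
          if (xp >= 0 && xp < d[0] && yp >= 0 && yp < d[1] &&
              zp >= 0 && zp < d[2] &&
              levels[idx3(xp, yp, zp, d)] == li)
            start = false;
          if (!start) continue;
          int len = 1;
          int xc = x + ox, yc = y + oy, zc = z + oz;
          while (xc >= 0 && xc < d[0] && yc >= 0 && yc < d[1] &&
                 zc >= 0 && zc < d[2] &&
                 levels[idx3(xc, yc, zc, d)] == li) {
            ++len; xc += ox; yc += oy; zc += oz;
          }
          if (len > maxrun) len = maxrun;
          out[(li - 1) + ng * (len - 1) + ng * maxrun * o] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxrun, nd);
  return out;
}

// Chebyshev distance to outside the mask (border voxels have distance 1),
// by multi-source BFS over the 26-neighbourhood.
// [[Rcpp::export]]
IntegerVector cpp_cheb_dist(IntegerVector mask, IntegerVector dim) {
  int d[3] = {dim[0], dim[1], dim[2]};
  int n = d[0] * d[1] * d[2];
  IntegerVector dist(n, NA_INTEGER);
  std::queue<int> q;
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int i = idx3(x, y, z, d);
        if (!mask[i]) continue;
        bool border = false;
        for (int dz = -1; dz <= 1 && !border; ++dz)
          for (int dy = -1; dy <= 1 && !border; ++dy)
            for (int dx = -1; dx <= 1 && !border; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= d[0] || y2 < 0 || y2 >= d[1] ||
                  z2 < 0 || z2 >= d[2] || !mask[idx3(x2, y2, z2, d)])
                border = true;
            }
        if (border) { dist[i] = 1; q.push(i); }
      }
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int z = i / (d[0] * d[1]);
    int rem = i - z * d[0] * d[1];
    int y = rem / d[0], x = rem - y * d[0];
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= d[0] || y2 < 0 || y2 >= d[1] ||
              z2 < 0 || z2 >= d[2]) continue;
          int j = idx3(x2, y2, z2, d);
          if (mask[j] && dist[j] == NA_INTEGER) {
            dist[j] = dist[i] + 1;
            q.push(j);
          }
        }
  }
  return dist;
}

// Connected zones of equal grey level (26-connectivity). Returns a matrix
// with one row per zone: level, size, minimum Chebyshev distance (if dist
// provided, else 0).
// [[Rcpp::export]]
IntegerMatrix cpp_zones(IntegerVector levels, IntegerVector dim,
                        Nullable<IntegerVector> dist_) {
  int d[3] = {dim[0], dim[1], dim[2]};
  int n = d[0] * d[1] * d[2];
  bool hasDist = dist_.isNotNull();
  IntegerVector dist;
  if (hasDist) dist = dist_.get();
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, zd;
  std::vector<int> stack;
  for (int i0 = 0; i0 < n; ++i0) {
    if (seen[i0] || levels[i0] == 0) continue;
    int lev = levels[i0];
    int size = 0, mind = INT_MAX;
    stack.clear(); stack.push_back(i0); seen[i0] = 1;
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      ++size;
      if (hasDist && dist[i] < mind) mind = dist[i];
      int z = i / (d[0] * d[1]);
      int rem = i - z * d[0] * d[1];
      int y = rem / d[0], x = rem - y * d[0];
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || x2 >= d[0] || y2 < 0 || y2 >= d[1] ||
                z2 < 0 || z2 >= d[2]) continue;
            int j = idx3(x2, y2, z2, d);
            if (!seen[j] && levels[j] == lev) {
              seen[j] = 1; stack.push_back(j);
            }
          }
    }
    zl.push_back(lev); zs.push_back(size);
    zd.push_back(hasDist ? mind : 0);
  }
  IntegerMatrix out(zl.size(), 3);
  for (size_t k = 0; k < zl.size(); ++k) {
    out(k, 0) = zl[k]; out(k, 1) = zs[k]; out(k, 2) = zd[k];
  }
  return out;
}

// NGTDM: per grey level, count n_i of in-mask voxels of that level and the
// summed absolute difference s_i between the level and the mean of its
// in-mask 26-neighbours (voxels with no in-mask neighbour are skipped).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  int d[3] = {dim[0], dim[1], dim[2]};
  NumericMatrix out(ng, 2);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int li = levels[idx3(x, y, z, d)];
        if (li == 0) continue;
        double sum = 0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= d[0] || y2 < 0 || y2 >= d[1] ||
                  z2 < 0 || z2 >= d[2]) continue;
              int lj = levels[idx3(x2, y2, z2, d)];
              if (lj == 0) continue;
              sum += lj; ++cnt;
            }
        if (cnt == 0) continue;
        out(li - 1, 0) += 1.0;
        out(li - 1, 1) += std::fabs(li - sum / cnt);
      }
  return out;
}

// NGLDM with coarseness parameter alpha: dependence count k of a voxel is
// the number of in-mask 26-neighbours whose level differs by <= alpha.
// Matrix entry (i, k+1).
// [[Rcpp::export]]
NumericMatrix cpp_ngldm(IntegerVector levels, IntegerVector dim, int ng,
                        int alpha) {
  int d[3] = {dim[0], dim[1], dim[2]};
  NumericMatrix out(ng, 27);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int li = levels[idx3(x, y, z, d)];
        if (li == 0) continue;
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= d[0] || y2 < 0 || y2 >= d[1] ||
                  z2 < 0 || z2 >= d[2]) continue;
              int lj = levels[idx3(x2, y2, z2, d)];
              if (lj != 0 && std::abs(lj - li) <= alpha) ++k;
            }
        out(li - 1, k) += 1.0;
      }
  return out;
}
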