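#include <Rcpp.h>
using namespace Rcpp;

// Sequential two-parameter Chinese-restaurant process: customer n+1 joins
// an existing class of size s with probability (s - alpha) / (n + theta)
// and opens a new class with probability (theta + K alpha) / (n + theta).
// Uses R's RNG so draws are reproducible under set.seed().
//
// [[Rcpp::export]]
IntegerVector crp_class_sizes_cpp(int N, double alpha, double theta) {
  if (N < 1) stop("N must be >= 1");
  if (alpha < 0.0 || alpha >= 1.0) stop("alpha must lie in [0, 1)");
  if (theta <= -alpha) stop("theta must exceed -alpha");

  std::vector<int> sizes;
  sizes.reserve(64);
  sizes.push_back(1);
  for (int n = 1; n < N; ++n) {
    int K = (int)sizes.size();
    double denom = n + theta;
    double u = unif_rand() * denom;
    // existing-class mass is n - K * alpha; anything beyond opens a class
    double acc = 0.0;
    int chosen = -1;
    double existing = n - K * alpha;
    if (u < existing) {
      for (int j = 0; j < K; ++j) {
        acc += sizes[j] - alpha;
        if (u < acc) { chosen = j; break; }
      }
      if (chosen < 0) chosen = K - 1;  // guard against float round-off
      sizes[chosen] += 1;
    } else {
      sizes.push_back(1);
    }
  }
  return wrap(sizes);
}

// Number of singleton classes in each of `reps` CRP draws of size N:
// the Monte Carlo oracle for the Pitman predictive singleton expectation.
//
// [[Rcpp::export]]
IntegerVector crp_singleton_counts_cpp(int reps, int N, double alpha, double theta) {
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    IntegerVector sizes = crp_class_sizes_cpp(N, alpha, theta);
    int m1 = 0;
    for (int j = 0; j < sizes.size(); ++j) if (sizes[j] == 1) ++m1;
    out[r] = m1;
  }
  return out;
}

// Number of classes in each of `reps` CRP draws (Ewens closed-form check).
//
// [[Rcpp::export]]
IntegerVector crp_num_classes_cpp(int reps, int N, double alpha, double theta) {
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    IntegerVector sizes = crp_class_sizes_cpp(N, alpha, theta);
    out[r] = sizes.size();
  }
  return out;
}
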