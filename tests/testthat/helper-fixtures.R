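# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# plain 4-window fully-alignable grid used by the hand-arithmetic tests
toy_windows <- function() {
  w <- build_windows(c(chr1 = 4e6), 1e6)
  filter_windows(w, "WGS")
}

# build a catalog data.frame from 0-based positions on one chromosome
toy_catalog <- function(pos0, chrom = "chr1", ref = "C", alt = "T",
                        variant_class = "SNV", context = "ACA") {
  n <- length(pos0)
  data.frame(chrom = rep(chrom, n), start = pos0, end = pos0 + 1,
             ref = rep(ref, n), alt = rep(alt, n),
             variant_class = rep(variant_class, n),
             context = rep(context, n), stringsAsFactors = FALSE)
}

# small fast classifier configuration used across classifier tests
small_config <- function(seed = 1, folds = 3, repeats = 2,
                         algorithm = "svm-rbf") {
  classifier_config(algorithm = algorithm, C_grid = c(1, 10),
                    gamma_grid = c(0.01, 0.1), cv_folds = folds,
                    cv_repeats = repeats, inner_folds = 2, seed = seed)
}

# the 4-class study cohort: 50 samples per class, well-separated profiles
acc_genome <- function() fixture("acc_genome", function() make_toy_genome(seed = 1))

acc_cohort <- function() fixture("acc_cohort", function() {
  g <- acc_genome()
  profiles <- default_profiles(g, n_classes = 4, seed = 1)
  generate_cohort(profiles, g$windows, g$regions, n_per_class = 50, seed = 1)
})

acc_rmd <- function() fixture("acc_rmd", function() {
  g <- acc_genome()
  build_feature_matrix(acc_cohort(), g$windows, g$regions, blocks = "RMD")
})

acc_ms96 <- function() fixture("acc_ms96", function() {
  g <- acc_genome()
  build_feature_matrix(acc_cohort(), g$windows, g$regions, blocks = "MS96")
})

# high-burden cohort for parameter-recovery checks (~1.2e5 mutations/class)
recovery_cohort <- function() fixture("recovery_cohort", function() {
  g <- acc_genome()
  profiles <- default_profiles(g, n_classes = 4, seed = 5,
                               burden_log_mean = log(2e4), burden_log_sd = 0.2)
  list(genome = g, profiles = profiles,
       cohort = generate_cohort(profiles, g$windows, g$regions,
                                n_per_class = 6, seed = 5))
})

# separable two-class gaussian toy for classifier unit tests
separable_toy <- function(n_per_class = 20, p = 5, shift = 6, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = shift), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- paste0("s", seq_len(2 * n_per_class))
  list(x = x, labels = rep(c("alpha", "beta"), each = n_per_class))
}
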