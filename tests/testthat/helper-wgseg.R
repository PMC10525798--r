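# Shared fixtures, all generated in code (no binary files in the repo).

# small thorax spec for fast tests (32 x 32)
tiny_spec <- function(noise_sigma = 0.03) {
  phantom_spec(height = 32, width = 32,
               lung_centers = list(left = c(15, 10), right = c(15, 22)),
               lung_axes = list(left = c(9, 5), right = c(9, 5)),
               heart_center = c(21, 13), heart_axes = c(5, 4),
               noise_sigma = noise_sigma)
}

tiny_gcfg <- function(num_labels = 4L)
  generator_config(base_filters = 8L, depth = 2L, se_reduction = 4L,
                   num_labels = num_labels)

tiny_ccfg <- function(side = 32L, k = 4L, norm = "layer", stages = 2L)
  critic_config(in_channels = 1L + k, base_filters = 8L, stages = stages,
                norm_kind = norm, input_side = side)

random_mask <- function(h, w, k, seed) {
  with_seed_test(seed, matrix(sample(0:(k - 1L), h * w, replace = TRUE),
                              h, w))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# independent brute-force confusion-count oracle: explicit pixel loop
oracle_counts <- function(pred, truth, label) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == label
      t <- truth[i, j] == label
      if (p && t) tp <- tp + 1L
      else if (p) fp <- fp + 1L
      else if (t) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# python + Pillow (available in the runtime image) as an independent PNG
# oracle
python_bin <- function() Sys.which("python")

# a fixed small dataset on disk, created once per test run
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "wgseg-shared-ds")
      man <- generate_dataset(8, tiny_spec(), jitter = 0.1, seed = 11,
                              out_dir = dir)
      cache <<- list(dir = dir, manifest = man)
    }
    cache
  }
})
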