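# Shared small fixtures, built once per test run.

local_fixtures <- new.env(parent = emptyenv())

small_phantom <- function(seed = 7L, grid = c(32L, 32L, 32L), n_rois = 24L,
                          n_classes = 4L) {
  key <- paste(seed, paste(grid, collapse = "x"), n_rois, n_classes, sep = "_")
  if (is.null(local_fixtures[[key]]))
    local_fixtures[[key]] <- make_phantom_atlas(seed, grid, n_rois, n_classes)
  local_fixtures[[key]]
}

small_sample <- function(seed = 7L, ...) {
  key <- paste("sample", seed, ..., sep = "_")
  if (is.null(local_fixtures[[key]]))
    local_fixtures[[key]] <- sample_image(small_phantom(), seed, ...)
  local_fixtures[[key]]
}

# tiny deterministic image volume
tiny_volume <- function(seed = 1, d = c(8L, 8L, 8L), voxel = 1) {
  v <- with_seed_test(seed, array(rnorm(prod(d), 100, 10), d))
  image_volume(v, voxel_size = rep(voxel, 3))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
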