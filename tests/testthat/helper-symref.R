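## Shared fixtures, built once per test run. The default phantom spec is the
## canonical study geometry; everything below is deterministic.
d5 <- point_group("D", 5)
c5 <- point_group("C", 5)

default_spec <- phantom_spec()
default_truth <- build_decamer_truth(default_spec)
default_map <- render_map(default_truth, default_spec)
default_mask_set <- default_masks(default_spec)

wall_only_map <- render_map(default_truth[default_truth$role == "wall", ],
                            default_spec)

random_map <- function(N, seed, voxel = 1) {
  set.seed(seed)
  density_map(array(rnorm(N^3), dim = c(N, N, N)), voxel)
}

## single-blob truth row for blob-level tests
blob_truth <- function(x, y, z, role = "wall") {
  data.frame(x = x, y = y, z = z, role = role, protomer = 1L,
             hemisphere = if (z >= 0) "N" else "S", site_class = "wall",
             stringsAsFactors = FALSE)
}

## normalized RMS difference between two grids
nrms <- function(a, b) sqrt(mean((a - b)^2)) / stats::sd(as.vector(a))
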