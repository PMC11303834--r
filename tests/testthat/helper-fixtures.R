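# Shared small fixtures, generated in code (no stored data).

# modest LV phantom for fast unit tests: 48^3, 20 um voxels
small_lv_phantom <- function(noise_sd = 0, seed = 3,
                             alpha_endo = 60, alpha_epi = -60) {
  generate_lv_phantom(lv_phantom_spec(
    shape = c(48, 48, 48), voxel_size_um = 20,
    inner_radius_um = 11 * 20, outer_radius_um = 20 * 20,
    alpha_endo_deg = alpha_endo, alpha_epi_deg = alpha_epi,
    noise_sd = noise_sd, seed = seed))
}

# axis-aligned flat slab with exact 10/100/20 voxel layers at 20 um
default_slab <- function(noise_sd = 0, seed = 1) {
  generate_wall_slab(wall_slab_spec(
    shape = c(24, 24, 160), voxel_size_um = 20,
    thickness_um = c(200, 2000, 400), noise_sd = noise_sd, seed = seed))
}

# separable sinusoidal texture volume f(z, y, x) = cos(k y) cos(k z)
# (no x variation): fiber direction should be x everywhere
yz_texture_volume <- function(n = 32, k = 2 * pi / 6) {
  iy <- array(rep(rep(0:(n - 1), each = n), times = n), c(n, n, n))
  iz <- array(rep(0:(n - 1), times = n * n), c(n, n, n))
  image_volume(cos(k * iy) * cos(k * iz), voxel_size_um = 1)
}

# seeded normal draw that leaves the global RNG untouched
with_seed_vec <- function(seed, n, mean = 0, sd = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rnorm(n, mean, sd)
}
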