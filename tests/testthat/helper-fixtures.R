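# Shared fixtures, built in code.

# A bare two-channel stack with everything zero except what the caller sets.
blank_stack <- function(dim = c(12, 10, 8), mask = NULL, z_spacing_nm = 260) {
  a <- array(0, dim)
  if (is.null(mask)) mask <- array(TRUE, dim)
  new_image_stack(a, a, mask, z_spacing_nm)
}

# A segmented nucleus built directly from a voxel coordinate matrix,
# bypassing segmentation — used to test the measurement operations against
# hand-computable supports.
nucleus_from_coords <- function(stack, coords, label = 1L) {
  d <- dim(stack$gfp)
  lin <- (coords[, 3] - 1L) * d[1] * d[2] + (coords[, 2] - 1L) * d[1] + coords[, 1]
  acvu:::new_segmented_nucleus(label, sort(lin), stack)
}

# A single-column nucleus spanning given slices at planar position (x, y),
# with per-slice GFP and mCherry values written into the stack.
column_nucleus_stack <- function(gfp_by_z, mch_by_z, x = 2L, y = 2L,
                                 dim = c(4, 4, length(gfp_by_z))) {
  gfp <- array(0, dim); mch <- array(0, dim)
  for (z in seq_along(gfp_by_z)) {
    gfp[x, y, z] <- gfp_by_z[z]
    mch[x, y, z] <- mch_by_z[z]
  }
  stack <- new_image_stack(gfp, mch, array(TRUE, dim))
  nuc <- nucleus_from_coords(stack, cbind(x, y, seq_along(gfp_by_z)))
  list(stack = stack, nucleus = nuc)
}

# One rendered synthetic animal under the default screen-stage condition.
demo_animal <- function(seed = 101, n_animals = 1, params = condition_lacz(n_animals)) {
  spec <- sample_condition(params, seed = seed)
  nuc <- spec[spec$animal_id == spec$animal_id[1], ]
  make_animal_image(nuc, seed = seed + 1)
}

# Independent enumeration oracle for the two-sided exact Mann-Whitney p:
# brute force over all group labelings.
mwu_enum_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- apply(utils::combn(n, nx), 2, function(ix) {
    sum(r[ix]) - nx * (nx + 1) / 2
  })
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Independent hypergeometric oracle for the two-sided Fisher p
# (probability method).
fisher_enum_p <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
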