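# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures on disk.

desk <- desk_scale_config()

# one small deterministic phantom per test file that needs a case
desk_case <- function(seed = 3, laterality = "left") {
  generate_phantom(desk$phantom, seed = seed, laterality = laterality)
}

# small random binary mask with <= n_fg foreground voxels
random_mask <- function(dims = c(8, 8, 6), n_fg = 20) {
  m <- array(0L, dims)
  k <- sample.int(n_fg, 1)
  m[sample.int(prod(dims), k)] <- 1L
  m
}

# brute-force O(|a||b|) symmetric Hausdorff oracle over all voxel pairs
hausdorff_bruteforce <- function(a, b, spacing = c(1, 1, 1)) {
  ca <- sweep(which(a != 0, arr.ind = TRUE), 2, spacing, `*`)
  cb <- sweep(which(b != 0, arr.ind = TRUE), 2, spacing, `*`)
  d <- as.matrix(dist(rbind(ca, cb)))[seq_len(nrow(ca)),
    nrow(ca) + seq_len(nrow(cb)),
    drop = FALSE
  ]
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

# brute-force per-voxel vote count oracle
vote_bruteforce <- function(preds) {
  out <- array(0L, dim(preds[[1]]))
  for (v in seq_along(out)) {
    out[v] <- sum(vapply(preds, function(p) p[v], integer(1)))
  }
  out
}

# digital ball mask centred in a grid
ball_mask <- function(dims, center, radius) {
  ix <- slice.index(array(0L, dims), 1)
  iy <- slice.index(array(0L, dims), 2)
  iz <- slice.index(array(0L, dims), 3)
  m <- ((ix - center[1])^2 + (iy - center[2])^2 + (iz - center[3])^2) <=
    radius^2
  array(as.integer(m), dims)
}

# simple constant-HU case with a ball organ inside a box body
toy_case <- function(dims = c(32, 32, 16), organ_center = NULL, radius = 4,
                     hu = 50) {
  if (is.null(organ_center)) organ_center <- (dims + 1) / 2
  organ <- ball_mask(dims, organ_center, radius)
  body <- array(1L, dims)
  img <- array(hu, dims) + organ * 15
  seg_case(
    image = ct_volume(img, spacing = c(1, 1, 2.5)),
    organ_mask = organ, body_mask = body,
    organ = "SMG", laterality = "left", case_id = "toy"
  )
}
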