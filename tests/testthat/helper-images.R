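# small image-building helpers shared by the suite

rgb_const <- function(r, g, b, h = 8, w = 8, bit_depth = 8L) {
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  oc_image(px, bit_depth = bit_depth)
}

rgb_from_planes <- function(r, g, b, bit_depth = 8L) {
  px <- array(0, dim = c(nrow(r), ncol(r), 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  oc_image(px, bit_depth = bit_depth)
}

full_mask <- function(h, w) matrix(TRUE, h, w)

# a tiny asymmetric pair whose dihedral orbit has 8 distinct elements
asym_pair <- function() {
  r <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  wli <- rgb_from_planes(r, r / 2, r / 3)
  afi <- rgb_from_planes(r / 2, r, r / 4)
  image_pair(wli, afi, case_id = "asym", mask = full_mask(2, 2))
}
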