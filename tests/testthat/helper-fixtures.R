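# brute-force all-pairs oracle for the shell-count statistic: every ordered
# pair's 3D distance, binned into [5i, 5(i+1)) for i = 2..9
brute_force_counts <- function(pattern) {
  n <- nrow(pattern$coords)
  if (n < 2L) return(rep(0, 8L))
  d <- as.matrix(dist(pattern$coords))
  d <- d[row(d) != col(d)]
  i <- floor(d / 5)
  vapply(2:9, function(k) sum(i == k), numeric(1L))
}

make_table <- function(frame, x, y, z = 0, accuracy = 20, roi = NULL,
                       pixel = 160) {
  localization_table(data.frame(frame = as.integer(frame), x = x, y = y,
                                z = z, accuracy = accuracy),
                     roi = roi, camera_pixel_nm = pixel)
}

# xy-shifted duplicate of a pattern as a two-stack localization table
two_stack_table <- function(pattern, shift) {
  d1 <- data.frame(frame = 0L, x = pattern$coords[, 1L],
                   y = pattern$coords[, 2L], z = pattern$coords[, 3L],
                   accuracy = 20)
  d2 <- transform(d1, frame = 1L, x = x + shift[1L], y = y + shift[2L])
  localization_table(rbind(d1, d2))
}
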