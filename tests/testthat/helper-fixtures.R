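# Analytic fixture tracks used across test files. All coordinates in um,
# frames 0-based, default frame interval 20 min.

straight_track <- function(n = 10, step = 2) {
  data.frame(frame = 0:(n - 1), x = step * (0:(n - 1)), y = 0)
}

# right-angle path (0,0) -> (3,0) -> (3,4): path 7, net 5
l_track <- function() {
  data.frame(frame = 0:2, x = c(0, 3, 3), y = c(0, 0, 4))
}

# closed unit-square loop ending at the start
square_track <- function() {
  data.frame(frame = 0:4, x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
}

random_track <- function(n = 20, seed = 1, scale = 5) {
  set.seed(seed)
  data.frame(frame = 0:(n - 1),
             x = cumsum(rnorm(n, 0, scale)),
             y = cumsum(rnorm(n, 0, scale)))
}

with_id <- function(track, id = "t1", group = "control") {
  track$track_id <- id
  track$group <- group
  track
}

write_generic_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# Minimal Imaris statistics export ("Position" sheet dialect): preamble
# lines, then the header row, then spot rows.
write_imaris_csv <- function(spots, path = tempfile(fileext = ".csv")) {
  lines <- c(
    "Position",
    "====================",
    "Position X,Position Y,Position Z,Unit,Category,Collection,Time,TrackID,ID",
    sprintf("%g,%g,0,um,Spot,Position,%d,%s,%d",
            spots$x, spots$y, spots$time, spots$track, seq_len(nrow(spots)))
  )
  writeLines(lines, path)
  path
}

# planted dwell episodes (>= min_len frames) from a simulated saltatory
# track's ground-truth state column
true_dwell_count <- function(states, min_len = 4) {
  r <- rle(states)
  sum(r$values == "dwell" & r$lengths >= min_len)
}
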