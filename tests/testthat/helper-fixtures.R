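# Shared fixtures and independent oracles used across the test files.

# Brute-force extremum-pairing oracle for noise-free rotation profiles:
# walks the theta signal, collects turning points (start, local extrema by
# first-difference sign change, end), keeps swings of magnitude >= amp_min,
# and greedily pairs consecutive opposite-signed swings in temporal order.
oracle_count_rotations <- function(theta, amp_min = 60) {
  tp <- theta[1]
  last_sign <- 0
  for (i in seq_len(length(theta) - 1)) {
    step <- theta[i + 1] - theta[i]
    if (step == 0) next
    sgn <- sign(step)
    if (last_sign != 0 && sgn != last_sign) tp <- c(tp, theta[i])
    last_sign <- sgn
  }
  tp <- c(tp, theta[length(theta)])
  swings <- diff(tp)
  swings <- swings[abs(swings) >= amp_min]
  if (length(swings) < 2) return(0L)
  count <- 0L
  i <- 1
  while (i <= length(swings)) {
    if (i + 1 <= length(swings) && sign(swings[i]) != sign(swings[i + 1])) {
      count <- count + 1L
      i <- i + 2
    } else i <- i + 1
  }
  count
}

# Random valid trajectory for I/O round-trip tests.
random_trajectory <- function(n = 40, fps = 30, hand = "right") {
  coords <- matrix(stats::runif(n * 63, -0.5, 0.5), nrow = n)
  hand_trajectory(coords, fps = fps, hand = hand)
}

# Random rotation-event list with the schema segment_rotations() emits.
random_events <- function(n, fps = 30) {
  if (n == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0), excursion_deg = numeric(0)))
  len <- sample(5:30, n, replace = TRUE)
  gap <- sample(0:3, n, replace = TRUE)
  start <- cumsum(c(0, (len + gap)[-n]))
  data.frame(start_frame = start, end_frame = start + len,
             duration_s = len / fps,
             excursion_deg = stats::runif(n, 120, 360))
}

# Minimal two-participant roster.
tiny_roster <- function() {
  data.frame(participant_id = c("Y01", "O01"),
             group = c("young", "older"), age = c(24, 70),
             gender = c("male", "female"),
             dominant_hand = c("right", "right"),
             education = c("college_plus", "middle_school"),
             ppt_1 = c(13, 8), ppt_2 = c(12, 8), ppt_3 = c(13, 9))
}
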