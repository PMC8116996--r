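# Internal clock/time helpers. All timestamps are POSIXct in UTC used as
# local wall-clock time; dates are `Date`; within-day positions are minutes
# from midnight (numeric, fractional allowed).

.as_instant <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}

# "08:30" -> 510
.hhmm_to_min <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
}

.min_to_hhmm <- function(m) {
  sprintf("%02d:%02d", floor(m / 60) %% 24, round(m) %% 60)
}

.date_of <- function(t) as.Date(t, tz = "UTC")

.midnight <- function(date) as.POSIXct(paste(date, "00:00:00"), tz = "UTC")

# minutes from midnight of the timestamp's own day
.min_of_day <- function(t) {
  as.numeric(difftime(t, .midnight(.date_of(t)), units = "mins"))
}

# Start of the anchored hour bin containing t. Bins are half-open
# [anchor + 60k, anchor + 60(k+1)) minutes; with the default anchor of 30
# the bins run 08:30-09:30, 09:30-10:30, ...
.bin_start <- function(t, anchor = 30) {
  secs <- as.numeric(t)
  a <- anchor * 60
  as.POSIXct(floor((secs - a) / 3600) * 3600 + a,
             origin = "1970-01-01", tz = "UTC")
}

.bin_label <- function(bin_start) format(bin_start, "%H:%M")

.wday_num <- function(date) {
  # 1 = Monday ... 7 = Sunday
  w <- as.POSIXlt(.midnight(date))$wday
  ifelse(w == 0L, 7L, w)
}

.wday_abb <- function(date) {
  c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[.wday_num(date)]
}

# Overlap in minutes between interval [s1, e1) and [s2, e2) (numeric minutes).
.overlap_min <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
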