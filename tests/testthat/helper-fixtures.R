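# shared fixtures: built in code, no files on disk

# the canonical 0-40 %B over 60 min linear analytical gradient
lin_gradient <- function() GradientProgram(c(0, 60), c(0, 40),
                                           label = "0-40%B/60min")

# quick scan table from parallel vectors; charges NA = unknown
make_table <- function(rt, tic = rep(1e6, length(rt)),
                       charge = rep(2L, length(rt)),
                       ms_level = rep(2L, length(rt)),
                       runId = "test-run", runLength = NA_real_) {
  ScanTable(data.frame(scan_id = sprintf("scan=%d", seq_along(rt)),
                       rt = rt, ms_level = ms_level, tic = tic,
                       precursor_charge = charge),
            runId = runId, runLength = runLength)
}

# independent oracle for the TIC-filter size: smallest k covering >= i% of m
oracle_keep_count <- function(i_percent, m) {
  k <- 0L
  while (k * 100 / m < i_percent) k <- k + 1L
  k
}
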