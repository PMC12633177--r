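# Shared fixture builders.

# two-subject recording whose channels have exactly the requested raw CVs
# (alternating base +/- 100*cv around a mean of 100, both wavelengths)
make_recording <- function(cvs, n = 200, fs. = 7.81) {
  nc <- length(cvs)
  intensity <- array(NA_real_, dim = c(n, nc, 2),
                     dimnames = list(NULL, NULL, c("760", "850")))
  for (ch in seq_len(nc)) {
    base <- rep(c(100 - 100 * cvs[ch], 100 + 100 * cvs[ch]), length.out = n)
    intensity[, ch, 1] <- base
    intensity[, ch, 2] <- base
  }
  chans <- data.frame(channel = seq_len(nc), source = seq_len(nc),
                      detector = seq_len(nc), type = "long", region = "x")
  structure(list(subjects = list(list(intensity = intensity, channels = chans),
                                 list(intensity = intensity, channels = chans)),
                 fs = fs., n = n, duration_s = n / fs.,
                 annotations = data.frame(task = "tangram", start = 0,
                                          end = n / fs.)),
            class = "dyad_recording")
}
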