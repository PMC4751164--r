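# Shared phantom fixtures, generated once per test run (generation is seeded
# and takes about a second each).

default_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_phantom(phantom_spec())
    ph
  }
})

default_fit <- local({
  fit <- NULL
  function() {
    ph <- default_phantom()
    if (is.null(fit))
      fit <<- detect_root_landmarks(ph$volume, ph$mesh, ph$centerline,
                                    root_control(debug = TRUE))
    fit
  }
})
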