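## Writes a small, fully synthetic input set (image, tracks, protrusions,
## condition table) into `dir` for pipeline-level tests.
make_pipeline_inputs <- function(dir) {
  ff <- generate_fiber_image(
    fiber_field_params(image_size_px = 128, n_fibers = 60,
                       mean_length_px = 60, width_px = 2,
                       orientation_kappa = 4, seed = 14,
                       fiber_intensity = 0.6),
    bg = background_params(speckle_sd = 0.04, seed = 14))
  write_image(ff$image, file.path(dir, "img.tif"))
  trs <- lapply(1:3, function(i) generate_trajectory(
    walk_params(n_steps = 40, seed = i), paste0("c", i)))
  write.csv(do.call(rbind, lapply(trs, as.data.frame)),
            file.path(dir, "tracks.csv"), row.names = FALSE)
  prs <- lapply(1:3, function(i) {
    ev <- as.data.frame(generate_protrusion_stream(
      protrusion_stream_params(axial_bias = 0.6, seed = i),
      paste0("c", i))$events)
    cbind(cell_id = paste0("c", i), ev)
  })
  pr <- do.call(rbind, prs)
  names(pr)[names(pr) == "time_min"] <- "t_min"
  write.csv(pr, file.path(dir, "prot.csv"), row.names = FALSE)
  cond <- data.frame(condition = c("1", "1.5", "2", "2.5"),
                     speed = c(0.9, 0.5, 0.3, 0.25),
                     alignment = c(0.8, 0.5, 0.35, 0.3))
  write.csv(cond, file.path(dir, "cond.csv"), row.names = FALSE)
  invisible(dir)
}
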