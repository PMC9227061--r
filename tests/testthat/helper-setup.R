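# small shared helpers: fast render/scene configurations for tests

small_render <- function(...) render_model(image_size = c(128, 128), ...)

small_scene <- function(n_cells = 5, speed_um_s = c(5, 15), ...) {
  make_scene(n_cells = n_cells, speed_um_s = speed_um_s,
             fov_um = c(64, 64), ...)
}

demoseq_path <- function()
  system.file("extdata", "demoseq.json", package = "platescope")

maxthroughput_path <- function()
  system.file("extdata", "maxthroughput.json", package = "platescope")
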