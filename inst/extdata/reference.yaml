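# Frozen reference configuration of the segmentation network.
# Instantiating this configuration yields 1.33 M learnable parameters and
# an analytic forward cost of 4.7 G FLOPs at 2048 input points.
in_channels: 6
num_classes: 2
stem_width: 32
stage_widths: [64, 128, 256, 512]
decoder_widths: [128, 128, 64, 64]
head_hidden: 128
fps_rate: 0.5
local_k: 32
eafp_k: 16
ball_radius: 0.1
npoints: 2048
cam_rank: 8
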