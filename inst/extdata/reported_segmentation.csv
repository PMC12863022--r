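class,total_images,total_instances,iou,precision,recall,f1
middle_turbinate,511,561,0.94,95.1,92.2,93.6
inferior_turbinate,361,383,0.86,90.6,87.1,88.8
mucus,376,759,0.70,85.0,72.3,78.2
overall,703,908,0.83,89.3,84.8,86.9
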