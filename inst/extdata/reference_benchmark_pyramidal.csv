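backbone,accuracy,recall,precision,f1
mobilenet_v2,95.14,96.86,93.65,95.22
alexnet,93.64,94.14,93.21,93.67
densenet201,94.00,94.43,93.63,94.03
googlenet,94.08,95.14,93.15,94.13
vgg16,91.71,91.00,92.32,91.65
resnet50,94.29,95.14,93.54,94.33
darknet19,92.57,91.86,93.19,92.52
squeezenet,90.93,91.57,90.41,90.99
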