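backbone,LD,QSVM,CSVM,FineKNN,BoT,BaT,MNN
alexnet,86.6,85.4,85.6,77.9,81.3,81.3,83.9
densenet201,86.6,88.2,88.1,83.0,82.7,80.9,87.4
googlenet,88.3,88.0,88.4,82.0,82.3,82.3,84.0
vgg16,85.9,84.6,84.0,81.6,79.8,78.5,82.8
mobilenet_v2,82.4,88.7,89.6,83.3,82.1,83.4,86.8
resnet50,85.9,88.7,87.9,82.8,83.2,81.1,86.5
darknet19,85.4,87.5,86.4,79.5,83.5,83.0,85.3
squeezenet,88.0,86.6,85.6,80.1,80.4,79.4,85.4
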